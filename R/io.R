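#' @title Delimited-text input/output for recordings, voltage and cycle tables
#' @description Readers accept comma- or tab-delimited text (the delimiter is
#'   auto-detected; ImageJ multi-measure exports vary between the two) and
#'   skip `#`-prefixed comment lines such as the run-manifest headers written
#'   by [run_pipeline()]. All writers emit comma-delimited text. Readers
#'   never silently drop rows; the number of data rows read is reported via
#'   a message when `options(motorsync.verbose = TRUE)`.
#' @name trace_io
NULL

detect_delim <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no data lines in ", path)
  n_tab <- sum(lengths(gregexpr("\t", lines, fixed = TRUE)) *
                 (regexpr("\t", lines, fixed = TRUE) > 0))
  n_comma <- sum(lengths(gregexpr(",", lines, fixed = TRUE)) *
                   (regexpr(",", lines, fixed = TRUE) > 0))
  if (n_tab > n_comma) "\t" else ","
}

read_table_checked <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (isTRUE(getOption("motorsync.verbose")))
    message("read ", nrow(df), " data row(s) from ", path)
  df
}

as_numeric_checked <- function(df, cols, path) {
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) &
                   !(trimws(df[[cn]]) %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value '", df[[cn]][bad[1]], "' at data row ", bad[1],
           ", column '", cn, "' of ", path)
    df[[cn]] <- v
  }
  df
}

#' Read a fluorescence recording from delimited text
#'
#' The trace file must have a header row of ROI identifiers and one row per
#' frame. An optional positions file supplies ROI centroids (`roi_id`,
#' `x_um`, `y_um`); its ROI set must match the trace header exactly.
#'
#' @param trace_path path to the frame-by-ROI intensity table.
#' @param sampling_rate_hz acquisition rate in frames per second.
#' @param positions_path optional path to the ROI centroid table.
#' @param stage_label,condition_label optional labels stored on the result.
#' @return a [fluorescence_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(trace_path, sampling_rate_hz, positions_path = NULL,
                           stage_label = NA_character_,
                           condition_label = NA_character_) {
  df <- read_table_checked(trace_path)
  if (!ncol(df)) stop("no ROI columns in ", trace_path)
  df <- as_numeric_checked(df, names(df), trace_path)
  positions <- NULL
  if (!is.null(positions_path)) {
    pos <- read_table_checked(positions_path)
    pos <- as_numeric_checked(pos, intersect(c("x_um", "y_um"), names(pos)),
                              positions_path)
    positions <- pos
  }
  fluorescence_recording(as.matrix(df), sampling_rate_hz,
                         roi_ids = names(df), positions = positions,
                         stage_label = stage_label,
                         condition_label = condition_label)
}

#' Write a fluorescence recording as delimited text
#'
#' @param recording a [fluorescence_recording()].
#' @param trace_path output path for the frame-by-ROI table (CSV).
#' @param positions_path optional output path for the centroid table;
#'   required if the recording carries positions and you want them kept.
#' @return invisibly, the recording.
#' @export
write_recording <- function(recording, trace_path, positions_path = NULL) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  utils::write.csv(as.data.frame(recording$frames), trace_path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(positions_path)) {
    if (is.null(recording$positions))
      stop("recording has no positions to write")
    utils::write.csv(recording$positions, positions_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(recording)
}

#' Read a voltage trace from delimited text
#'
#' Accepts either a single `vm_mv` column or a `time_s, vm_mv` pair. A time
#' column, when present, must be strictly increasing and consistent with
#' the stated sampling rate to within 1%.
#'
#' @param path input file.
#' @param sampling_rate_hz acquisition rate in samples per second.
#' @return a [voltage_trace()].
#' @export
read_voltage <- function(path, sampling_rate_hz) {
  df <- read_table_checked(path)
  df <- as_numeric_checked(df, names(df), path)
  if ("time_s" %in% names(df)) {
    tt <- df$time_s
    if (any(diff(tt) <= 0))
      stop("time_s column is not strictly increasing at data row ",
           which(diff(tt) <= 0)[1] + 1L, " of ", path)
    implied <- 1 / stats::median(diff(tt))
    if (abs(implied - sampling_rate_hz) / sampling_rate_hz > 0.01)
      stop(sprintf(
        "time column implies %.4g Hz but sampling_rate_hz = %.4g (>1%% off)",
        implied, sampling_rate_hz))
    vm <- df$vm_mv %||% df[[setdiff(names(df), "time_s")[1]]]
  } else {
    vm <- df[[if ("vm_mv" %in% names(df)) "vm_mv" else names(df)[1]]]
  }
  voltage_trace(vm, sampling_rate_hz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a voltage trace as delimited text
#'
#' @param trace a [voltage_trace()].
#' @param path output path; written with `time_s` and `vm_mv` columns.
#' @return invisibly, the trace.
#' @export
write_voltage <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  df <- data.frame(
    time_s = (seq_along(trace$vm_mv) - 1L) / trace$sampling_rate_hz,
    vm_mv = trace$vm_mv)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(trace)
}

#' Write a cycle table as CSV
#'
#' Rows are ordered deterministically by `roi_id`, then `onset_frame`.
#'
#' @param cycles a cycle data frame (see [empty_cycles()] for the schema).
#' @param path output path.
#' @return invisibly, the reordered cycle table that was written.
#' @seealso [read_cycles()]
#' @export
write_cycles <- function(cycles, path) {
  cycles <- validate_cycles(as.data.frame(cycles))
  cols <- c("roi_id", "onset_frame", "duration_frames", "peak_frame",
            "amplitude", "snr", "sync_label")
  cycles <- cycles[order(cycles$roi_id, cycles$onset_frame), cols, drop = FALSE]
  rownames(cycles) <- NULL
  utils::write.csv(cycles, path, row.names = FALSE, quote = FALSE)
  invisible(cycles)
}

#' Read a cycle table written by [write_cycles()]
#'
#' @param path input file.
#' @return cycle data frame.
#' @export
read_cycles <- function(path) {
  df <- read_table_checked(path)
  if (!nrow(df))
    return(empty_cycles())
  df <- as_numeric_checked(
    df, c("onset_frame", "duration_frames", "peak_frame", "amplitude", "snr"),
    path)
  for (cn in c("onset_frame", "duration_frames", "peak_frame"))
    df[[cn]] <- as.integer(df[[cn]])
  validate_cycles(df)
}
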