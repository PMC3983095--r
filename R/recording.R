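#' Fluorescence recording object
#'
#' Container for a population calcium-imaging recording: a frame-by-ROI
#' intensity matrix sampled at a uniform rate, with optional ROI centroid
#' positions and free-text stage/condition labels. Intensities are kept in
#' arbitrary fluorescence units; no delta-F/F conversion is applied because
#' the cycle detector thresholds per-trace statistics of the differential
#' and is therefore covariant under affine rescaling of each trace.
#'
#' @param frames numeric matrix, one row per frame, one column per ROI.
#' @param sampling_rate_hz frames per second (> 0); population imaging in
#'   this system is typically acquired at 1 Hz.
#' @param roi_ids character vector of ROI identifiers, one per column.
#'   Defaults to the column names of `frames`, or `roi_1 ... roi_n`.
#' @param positions optional data frame with columns `roi_id`, `x_um`,
#'   `y_um` giving each ROI centroid in micrometres; must cover exactly the
#'   ROIs present in `frames`.
#' @param stage_label,condition_label optional free-text labels (e.g.
#'   `"HH26"`, `"baseline"`).
#'
#' @return An object of class `fluorescence_recording`: a list with fields
#'   `frames`, `sampling_rate_hz`, `roi_ids`, `positions`, `stage_label`,
#'   `condition_label`.
#' @examples
#' rec <- fluorescence_recording(matrix(rnorm(1200, 100), 600, 2), 1)
#' n_frames(rec)
#' duration_s(rec)
#' @export
fluorescence_recording <- function(frames, sampling_rate_hz, roi_ids = NULL,
                                   positions = NULL, stage_label = NA_character_,
                                   condition_label = NA_character_) {
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (nrow(frames) < 2L)
    stop("a recording needs at least 2 frames, got ", nrow(frames))
  if (!all(is.finite(frames)))
    stop("all intensities must be finite; found ",
         sum(!is.finite(frames)), " non-finite value(s)")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  if (is.null(roi_ids)) {
    roi_ids <- colnames(frames)
    if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(ncol(frames)))
  }
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != ncol(frames))
    stop("roi_ids length (", length(roi_ids), ") != number of trace columns (",
         ncol(frames), ")")
  if (anyDuplicated(roi_ids))
    stop("duplicated roi_ids: ", paste(unique(roi_ids[duplicated(roi_ids)]), collapse = ", "))
  colnames(frames) <- roi_ids
  if (!is.null(positions)) positions <- validate_positions(positions, roi_ids)
  structure(
    list(frames = frames, sampling_rate_hz = sampling_rate_hz,
         roi_ids = roi_ids, positions = positions,
         stage_label = stage_label, condition_label = condition_label),
    class = "fluorescence_recording")
}

validate_positions <- function(positions, roi_ids) {
  positions <- as.data.frame(positions)
  need <- c("roi_id", "x_um", "y_um")
  if (!all(need %in% names(positions)))
    stop("positions must have columns roi_id, x_um, y_um")
  positions$roi_id <- as.character(positions$roi_id)
  extra <- setdiff(positions$roi_id, roi_ids)
  missing <- setdiff(roi_ids, positions$roi_id)
  if (length(extra) || length(missing))
    stop("positions/trace ROI sets disagree",
         if (length(extra)) paste0("; in positions only: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; in traces only: ", paste(missing, collapse = ", ")))
  if (!all(is.finite(positions$x_um)) || !all(is.finite(positions$y_um)))
    stop("ROI positions must be finite")
  # one row per ROI, in trace column order
  positions <- positions[match(roi_ids, positions$roi_id), need, drop = FALSE]
  rownames(positions) <- NULL
  positions
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d frames x %d ROIs at %g Hz (%.1f min)\n",
              nrow(x$frames), ncol(x$frames), x$sampling_rate_hz,
              duration_s(x) / 60))
  if (!is.na(x$stage_label)) cat("  stage:     ", x$stage_label, "\n")
  if (!is.na(x$condition_label)) cat("  condition: ", x$condition_label, "\n")
  cat("  positions: ", if (is.null(x$positions)) "absent" else "present", "\n")
  invisible(x)
}

#' Number of frames in a recording
#' @param recording a [fluorescence_recording()].
#' @return integer frame count.
#' @export
n_frames <- function(recording) nrow(recording$frames)

#' Recording duration in seconds
#' @param recording a [fluorescence_recording()] or [voltage_trace()].
#' @return duration in seconds (samples / rate).
#' @export
duration_s <- function(recording) {
  if (inherits(recording, "voltage_trace"))
    return(length(recording$vm_mv) / recording$sampling_rate_hz)
  nrow(recording$frames) / recording$sampling_rate_hz
}

#' Extract one ROI trace
#' @param recording a [fluorescence_recording()].
#' @param roi ROI identifier.
#' @return numeric vector of per-frame intensities.
#' @export
roi_trace <- function(recording, roi) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  if (!roi %in% recording$roi_ids)
    stop("unknown ROI '", roi, "'")
  recording$frames[, roi]
}

#' Single-neuron voltage trace object
#'
#' Membrane potential sampled at a uniform (typically 1 kHz) rate.
#'
#' @param vm_mv numeric vector of membrane potential in mV.
#' @param sampling_rate_hz samples per second (> 0).
#' @return An object of class `voltage_trace`.
#' @examples
#' vt <- voltage_trace(rnorm(5000, -48), 1000)
#' duration_s(vt)
#' @export
voltage_trace <- function(vm_mv, sampling_rate_hz) {
  vm_mv <- as.numeric(vm_mv)
  if (length(vm_mv) < 2L) stop("voltage trace needs at least 2 samples")
  if (!all(is.finite(vm_mv))) stop("all voltage samples must be finite")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  structure(list(vm_mv = vm_mv, sampling_rate_hz = sampling_rate_hz),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples at %g Hz (%.1f s), mean %.1f mV\n",
              length(x$vm_mv), x$sampling_rate_hz, duration_s(x),
              mean(x$vm_mv)))
  invisible(x)
}

#' Empty cycle table
#'
#' Cycles are represented throughout the package as a data frame with one
#' row per detected cycle. Frames are 0-based and cycle intervals half-open:
#' a cycle occupies frames `[onset_frame, onset_frame + duration_frames)`.
#'
#' @return zero-row data frame with columns `roi_id`, `onset_frame`,
#'   `duration_frames`, `peak_frame`, `amplitude`, `snr`, `sync_label`.
#' @export
empty_cycles <- function() {
  data.frame(roi_id = character(), onset_frame = integer(),
             duration_frames = integer(), peak_frame = integer(),
             amplitude = double(), snr = double(),
             sync_label = character(), stringsAsFactors = FALSE)
}

validate_cycles <- function(cycles, n_frames = NULL) {
  need <- c("roi_id", "onset_frame", "duration_frames", "peak_frame",
            "amplitude")
  if (!all(need %in% names(cycles)))
    stop("cycle table lacks column(s): ",
         paste(setdiff(need, names(cycles)), collapse = ", "))
  if (!"snr" %in% names(cycles)) cycles$snr <- NA_real_
  if (!"sync_label" %in% names(cycles)) cycles$sync_label <- "unclassified"
  if (nrow(cycles)) {
    stopifnot(all(cycles$onset_frame >= 0), all(cycles$duration_frames >= 1),
              all(cycles$peak_frame >= cycles$onset_frame),
              all(cycles$peak_frame < cycles$onset_frame + cycles$duration_frames))
    if (!is.null(n_frames) &&
        any(cycles$onset_frame + cycles$duration_frames > n_frames))
      stop("cycle extends past the last frame")
  }
  cycles
}
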