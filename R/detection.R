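#' Cycle-detection parameters
#'
#' The detector thresholds the first differential of a fluorescence trace
#' at `sd_multiplier` standard deviations above its mean, both computed
#' over the whole trace (signal frames included; the rule is deliberately
#' per-trace so detection is covariant under affine rescaling of the
#' trace). At the native 1 Hz rate no smoothing is applied; a centred
#' moving-average window is exposed for higher-rate or noisier data.
#'
#' @param sd_multiplier threshold in standard deviations of the
#'   differential (> 0, default 2).
#' @param smooth_window_frames odd moving-average width applied before
#'   differencing (default 1 = none).
#' @param min_duration_frames discard cycles shorter than this (default 1,
#'   i.e. keep everything: at 1 Hz genuinely shorter events are invisible
#'   anyway).
#' @param merge_gap_frames merge consecutive cycles separated by fewer
#'   than this many frames (default 0 = never).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(sd_multiplier = 2, smooth_window_frames = 1L,
                             min_duration_frames = 1L, merge_gap_frames = 0L) {
  stopifnot(sd_multiplier > 0,
            smooth_window_frames >= 1, smooth_window_frames %% 2 == 1,
            min_duration_frames >= 1, merge_gap_frames >= 0)
  structure(list(sd_multiplier = sd_multiplier,
                 smooth_window_frames = as.integer(smooth_window_frames),
                 min_duration_frames = as.integer(min_duration_frames),
                 merge_gap_frames = as.integer(merge_gap_frames)),
            class = "detection_params")
}

#' First differential of a trace
#'
#' Optionally smooths with a centred moving average (truncated to the
#' available samples at the edges), then takes the first difference
#' `d[t] = s[t] - s[t-1]`, with `d[1] = 0` so the output has the same
#' length as the input.
#'
#' @param trace numeric vector, length >= 2 and >= `smooth_window_frames`.
#' @param smooth_window_frames odd moving-average width (1 = none).
#' @return numeric vector of the same length as `trace`.
#' @examples
#' differentiate(c(0, 1, 3, 6))   # 0 1 2 3
#' @export
differentiate <- function(trace, smooth_window_frames = 1L) {
  n <- length(trace)
  if (n < 2L) stop("trace must have at least 2 frames")
  w <- as.integer(smooth_window_frames)
  if (w %% 2 != 1 || w < 1) stop("smooth_window_frames must be odd and >= 1")
  if (n < w) stop("trace shorter than smoothing window")
  s <- if (w > 1L) moving_average(trace, w) else trace
  c(0, diff(s))
}

# centred moving average; the window is truncated at the trace edges so no
# frames are lost
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect calcium cycles in one or all ROI traces
#'
#' A cycle onset is the first frame of each maximal run where the first
#' differential exceeds `mean + sd_multiplier * sd` of the differential.
#' Scanning forward from the onset, the cycle lasts until the first frame
#' at which the differential, having gone negative (i.e. passed through a
#' local minimum), returns to a value >= 0; a cycle still open at the end
#' of the trace is closed at the final frame. Onsets are never raised
#' inside an open cycle, so returned cycles are non-overlapping and sorted
#' by onset.
#'
#' Amplitude is the peak intensity within the cycle minus the intensity
#' at the cycle's rise onset. Because the differential first exceeds the
#' threshold at the frame *after* fluorescence starts rising (at 1 Hz the
#' ~1 s rise completes within a single inter-frame step), the pre-rise
#' intensity is taken at the frame immediately before the onset frame
#' (or at the onset frame itself when the cycle starts the trace);
#' anchoring it at the onset frame instead would subtract an
#' already-risen value and report near-zero amplitudes for fast
#' transients.
#'
#' A trace whose differential has zero variance admits no threshold
#' crossing; an empty table is returned with a warning.
#'
#' @param recording a [fluorescence_recording()].
#' @param params a [detection_params()].
#' @param roi a single ROI identifier, or `NULL` (default) to run the
#'   detector on every ROI and return the combined table.
#' @return cycle data frame (see [empty_cycles()]); frames 0-based, cycle
#'   intervals half-open `[onset, onset + duration)`. `snr` is `NA` until
#'   filled by [compute_snr()]; `sync_label` is `"unclassified"` until set
#'   by [label_cycles()].
#' @examples
#' tr <- c(10, 10, 10, 10, 18, 24, 24, 22, 20, 18, 16, 14, 12, 11, 11, 11)
#' rec <- fluorescence_recording(cbind(a = tr), 1)
#' detect_cycles(rec)
#' @export
detect_cycles <- function(recording, params = detection_params(), roi = NULL) {
  stopifnot(inherits(recording, "fluorescence_recording"),
            inherits(params, "detection_params"))
  rois <- if (is.null(roi)) recording$roi_ids else as.character(roi)
  bad <- setdiff(rois, recording$roi_ids)
  if (length(bad)) stop("unknown ROI(s): ", paste(bad, collapse = ", "))
  out <- lapply(rois, function(r)
    detect_cycles_trace(recording$frames[, r], r, params))
  out <- do.call(rbind, c(list(empty_cycles()), out))
  rownames(out) <- NULL
  out
}

detect_cycles_trace <- function(trace, roi_id, params) {
  n <- length(trace)
  if (n < 3L) stop("trace must have at least 3 frames for detection")
  d <- differentiate(trace, params$smooth_window_frames)
  sig <- stats::sd(d)
  if (sig == 0) {
    warning("zero-variance differential for ROI '", roi_id,
            "'; no cycles detectable")
    return(empty_cycles())
  }
  thr <- mean(d) + params$sd_multiplier * sig

  above <- d > thr
  if (!any(above)) return(empty_cycles())
  run_starts <- which(above & !c(FALSE, above[-n]))

  onsets <- integer(0)
  ends <- integer(0)          # 1-based offset frame (exclusive in raster terms)
  pos <- 1L                   # first 1-based index eligible as an onset
  for (o in run_starts) {
    if (o < pos) next         # falls inside the previous (open) cycle
    u <- o + 1L
    seen_neg <- FALSE
    closed <- FALSE
    while (u <= n) {
      if (d[u] < 0) seen_neg <- TRUE
      else if (seen_neg) { closed <- TRUE; break }
      u <- u + 1L
    }
    if (!closed) u <- n       # still open at the final frame
    onsets <- c(onsets, o)
    ends <- c(ends, max(u, o + 1L))
    pos <- max(u, o + 1L)
  }

  # merge cycles separated by fewer than merge_gap_frames
  if (params$merge_gap_frames > 0L && length(onsets) > 1L) {
    keep_on <- onsets[1]; keep_end <- ends[1]
    m_on <- integer(0); m_end <- integer(0)
    for (i in seq_along(onsets)[-1]) {
      if (onsets[i] - keep_end < params$merge_gap_frames) {
        keep_end <- ends[i]
      } else {
        m_on <- c(m_on, keep_on); m_end <- c(m_end, keep_end)
        keep_on <- onsets[i]; keep_end <- ends[i]
      }
    }
    onsets <- c(m_on, keep_on); ends <- c(m_end, keep_end)
  }

  dur <- ends - onsets
  keep <- dur >= params$min_duration_frames
  onsets <- onsets[keep]; ends <- ends[keep]; dur <- dur[keep]
  if (!length(onsets)) return(empty_cycles())

  peak <- vapply(seq_along(onsets), function(i) {
    idx <- onsets[i]:(ends[i] - 1L)
    idx[which.max(trace[idx])]
  }, integer(1))
  pre <- trace[pmax(onsets - 1L, 1L)]   # last pre-rise frame

  data.frame(roi_id = roi_id,
             onset_frame = onsets - 1L,               # to 0-based
             duration_frames = as.integer(dur),
             peak_frame = peak - 1L,
             amplitude = trace[peak] - pmin(pre, trace[onsets]),
             snr = NA_real_,
             sync_label = "unclassified",
             stringsAsFactors = FALSE)
}

#' Per-cycle signal-to-noise ratio
#'
#' SNR of a cycle is its amplitude divided by the standard deviation of the
#' trace over all frames outside any cycle of the same ROI. When the trace
#' has no out-of-cycle frames the SNR is undefined and reported as `NA`;
#' when the out-of-cycle trace is exactly constant (noise-free synthetic
#' data) it is reported as `Inf`. Both are detectable with `is.finite()`.
#'
#' @param recording a [fluorescence_recording()].
#' @param roi ROI identifier the cycles belong to.
#' @param cycles cycle data frame for this ROI.
#' @return numeric vector of per-cycle SNR values, aligned with the rows
#'   of `cycles`.
#' @export
compute_snr <- function(recording, roi, cycles) {
  trace <- roi_trace(recording, roi)
  cycles <- validate_cycles(cycles, length(trace))
  if (!nrow(cycles)) return(double(0))
  if (!all(cycles$roi_id == roi)) stop("cycles are not all from ROI '", roi, "'")
  inside <- rep(FALSE, length(trace))
  for (i in seq_len(nrow(cycles))) {
    a <- cycles$onset_frame[i] + 1L
    b <- cycles$onset_frame[i] + cycles$duration_frames[i]
    inside[a:b] <- TRUE
  }
  out <- trace[!inside]
  if (length(out) < 2L) return(rep(NA_real_, nrow(cycles)))
  s <- stats::sd(out)
  if (s == 0) return(ifelse(cycles$amplitude > 0, Inf, NA_real_))
  cycles$amplitude / s
}

#' Annotate a cycle table with SNR for every ROI
#'
#' Convenience wrapper applying [compute_snr()] ROI by ROI.
#'
#' @inheritParams compute_snr
#' @param cycles combined cycle data frame (any number of ROIs).
#' @return the cycle table with its `snr` column filled.
#' @export
annotate_snr <- function(recording, cycles) {
  cycles <- validate_cycles(cycles, n_frames(recording))
  for (r in unique(cycles$roi_id)) {
    sel <- cycles$roi_id == r
    cycles$snr[sel] <- compute_snr(recording, r, cycles[sel, , drop = FALSE])
  }
  cycles
}

#' Filter detected cycles by signal-to-noise ratio
#'
#' A per-trace 2 sd threshold on the differential necessarily crosses on
#' a few percent of frames of any noisy trace, so raw detections on real
#' (or noisy synthetic) data include spurious short, low-amplitude
#' cycles — including on completely silent neurons. Genuine calcium
#' transients separate cleanly from these by SNR, so the standard
#' analysis discards cycles below `snr_min` before any population
#' statistic. SNR is computed first (via [annotate_snr()]) if missing.
#' Cycles with infinite SNR (noise-free traces) are kept; cycles with
#' undefined SNR (no out-of-cycle frames) are kept conservatively.
#'
#' @param recording a [fluorescence_recording()].
#' @param cycles cycle data frame.
#' @param snr_min keep cycles with SNR >= this (default 6, midway on a
#'   log scale between the SNR of spurious threshold crossings on pure
#'   noise, about 2-5, and of genuine transients at realistic indicator
#'   signal-to-noise, 10 or more; set 0 to keep everything).
#' @return the filtered cycle table (SNR column filled).
#' @export
filter_cycles_snr <- function(recording, cycles, snr_min = 6) {
  cycles <- validate_cycles(cycles, n_frames(recording))
  if (snr_min <= 0) return(cycles)
  if (anyNA(cycles$snr) && nrow(cycles))
    cycles <- annotate_snr(recording, cycles)
  keep <- is.na(cycles$snr) | cycles$snr >= snr_min
  out <- cycles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a binary event raster from detected cycles
#'
#' The raster has one row per frame and one column per ROI of the
#' recording (including inactive ROIs); entry `[t, i]` is 1 exactly when
#' 0-based frame `t - 1` lies inside some cycle of ROI `i`.
#'
#' @param recording a [fluorescence_recording()].
#' @param cycles cycle data frame; cycles of a single ROI must not overlap.
#' @return an object of class `event_raster`: list with `occupancy`
#'   (integer matrix frame x ROI), `roi_ids`, `sampling_rate_hz`.
#' @export
build_raster <- function(recording, cycles) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  cycles <- validate_cycles(cycles, n_frames(recording))
  bad <- setdiff(unique(cycles$roi_id), recording$roi_ids)
  if (length(bad)) stop("cycles reference unknown ROI(s): ",
                        paste(bad, collapse = ", "))
  occ <- matrix(0L, n_frames(recording), length(recording$roi_ids),
                dimnames = list(NULL, recording$roi_ids))
  for (i in seq_len(nrow(cycles))) {
    a <- cycles$onset_frame[i] + 1L
    b <- cycles$onset_frame[i] + cycles$duration_frames[i]
    col <- cycles$roi_id[i]
    if (any(occ[a:b, col] == 1L))
      stop("overlapping cycles on ROI '", col,
           "': detector contract violated")
    occ[a:b, col] <- 1L
  }
  structure(list(occupancy = occ, roi_ids = recording$roi_ids,
                 sampling_rate_hz = recording$sampling_rate_hz),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d frames x %d ROIs at %g Hz, %.1f%% occupied\n",
              nrow(x$occupancy), ncol(x$occupancy), x$sampling_rate_hz,
              100 * mean(x$occupancy)))
  invisible(x)
}
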