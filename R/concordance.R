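#' Voltage cycle-detection parameters
#'
#' Cycles in an intracellular trace are sustained depolarisations above a
#' running-median baseline. Sub-second depolarisations — which have no
#' calcium-imaging counterpart at 1 Hz — are excluded by the minimum
#' duration. The baseline window is chosen much longer than a cycle
#' (~2.7 s) but much shorter than the interval between episodes (minutes),
#' so the median is robust to the events themselves.
#'
#' @param depol_threshold_mv depolarisation above baseline required (mV,
#'   default 10).
#' @param min_duration_s minimum event length counting as a cycle
#'   (default 1.0 s).
#' @param baseline_window_s running-median window (default 30 s).
#' @return an object of class `voltage_cycle_params`.
#' @export
voltage_cycle_params <- function(depol_threshold_mv = 10, min_duration_s = 1,
                                 baseline_window_s = 30) {
  stopifnot(depol_threshold_mv > 0, min_duration_s > 0, baseline_window_s > 0)
  structure(list(depol_threshold_mv = depol_threshold_mv,
                 min_duration_s = min_duration_s,
                 baseline_window_s = baseline_window_s),
            class = "voltage_cycle_params")
}

#' Detect cycles in a voltage trace
#'
#' Candidate events are maximal runs of samples exceeding the running
#' median baseline by `depol_threshold_mv`; runs shorter than
#' `min_duration_s` (the "small depolarisations") are discarded.
#'
#' @param trace a [voltage_trace()], at least twice the baseline window.
#' @param params a [voltage_cycle_params()].
#' @return data frame with one row per cycle: `onset_s`, `duration_s`,
#'   `onset_sample`, `duration_samples` (0-based, half-open), `peak_mv`,
#'   `amplitude_mv` (peak minus baseline at onset).
#' @export
detect_voltage_cycles <- function(trace, params = voltage_cycle_params()) {
  stopifnot(inherits(trace, "voltage_trace"),
            inherits(params, "voltage_cycle_params"))
  vm <- trace$vm_mv
  rate <- trace$sampling_rate_hz
  if (length(vm) < 2 * params$baseline_window_s * rate)
    stop("trace must be at least twice the baseline window (",
         2 * params$baseline_window_s, " s)")
  # the baseline varies on the window scale (>= seconds), far below the
  # sampling rate, so the running median is computed on a decimated trace
  # and linearly interpolated back; exact for any baseline drift slower
  # than the decimation step
  win <- params$baseline_window_s * rate
  step <- max(1L, as.integer(floor(win / 1000)))
  sub_idx <- seq(1L, length(vm), by = step)
  k <- as.integer(round(win / step))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(sub_idx) - (1L - length(sub_idx) %% 2L))
  base_sub <- stats::runmed(vm[sub_idx], k, endrule = "median")
  baseline <- if (step == 1L) base_sub else
    stats::approx(sub_idx, base_sub, xout = seq_along(vm), rule = 2)$y
  above <- vm > baseline + params$depol_threshold_mv
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= params$min_duration_s * rate)
  if (!length(keep))
    return(data.frame(onset_s = double(), duration_s = double(),
                      onset_sample = integer(), duration_samples = integer(),
                      peak_mv = double(), amplitude_mv = double()))
  onset <- starts[keep]
  dur <- r$lengths[keep]
  peak <- vapply(seq_along(onset), function(i)
    max(vm[onset[i]:(onset[i] + dur[i] - 1L)]), double(1))
  data.frame(onset_s = (onset - 1L) / rate,
             duration_s = dur / rate,
             onset_sample = onset - 1L,
             duration_samples = as.integer(dur),
             peak_mv = peak,
             amplitude_mv = peak - baseline[onset])
}

#' Match optically detected cycles to voltage cycles
#'
#' Greedy one-to-one matching in time order: each calcium cycle is paired
#' with the nearest still-unmatched voltage cycle whose onset lies within
#' `tolerance_s`; ties break toward the earlier voltage cycle. Events in
#' this preparation are sparse (about one per minute) so greedy matching
#' is equivalent to optimal assignment in practice. Onset accuracy is the
#' percentage of calcium cycles with a voltage counterpart; duration
#' ratios (optical / voltage) quantify the slower return of the calcium
#' indicator.
#'
#' @param ca_cycles calcium cycle data frame (frames at `ca_rate_hz`).
#' @param v_cycles voltage cycle table from [detect_voltage_cycles()].
#' @param ca_rate_hz imaging rate the calcium cycles were detected at.
#' @param tolerance_s onset matching window in seconds (default 2: the
#'   onset-to-peak time is about 1 s at 1 Hz sampling, so a two-frame
#'   window absorbs discretisation without conflating distinct episodes).
#' @return an object of class `match_result`: list with `n_ca_cycles`,
#'   `n_v_cycles`, `n_matched`, `onset_accuracy_percent` (`NA` when there
#'   are no calcium cycles), `tolerance_s`, and per-match table `matches`
#'   (`ca_onset_s`, `v_onset_s`, `onset_diff_s`, `length_ratio`).
#' @export
match_events <- function(ca_cycles, v_cycles, ca_rate_hz, tolerance_s = 2) {
  ca_cycles <- validate_cycles(ca_cycles)
  stopifnot(tolerance_s > 0, ca_rate_hz > 0)
  ca_on <- sort(ca_cycles$onset_frame) / ca_rate_hz
  ord <- order(ca_cycles$onset_frame)
  ca_dur <- (ca_cycles$duration_frames / ca_rate_hz)[ord]
  v_on <- v_cycles$onset_s
  v_dur <- v_cycles$duration_s
  used <- rep(FALSE, length(v_on))
  rows <- list()
  for (i in seq_along(ca_on)) {
    cand <- which(!used & abs(v_on - ca_on[i]) <= tolerance_s)
    if (!length(cand)) next
    # nearest onset; tie toward the earlier voltage cycle
    dd <- abs(v_on[cand] - ca_on[i])
    j <- cand[order(dd, v_on[cand])][1]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      ca_onset_s = ca_on[i], v_onset_s = v_on[j],
      onset_diff_s = ca_on[i] - v_on[j],
      length_ratio = ca_dur[i] / v_dur[j])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ca_onset_s = double(), v_onset_s = double(),
               onset_diff_s = double(), length_ratio = double())
  n_ca <- length(ca_on)
  structure(list(
    n_ca_cycles = n_ca, n_v_cycles = length(v_on),
    n_matched = nrow(matches),
    onset_accuracy_percent = if (n_ca) 100 * nrow(matches) / n_ca else NA_real_,
    tolerance_s = tolerance_s, matches = matches),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d calcium cycles matched (%s%%), %d voltage cycles\n",
              x$n_matched, x$n_ca_cycles,
              if (is.na(x$onset_accuracy_percent)) "NA"
              else sprintf("%.1f", x$onset_accuracy_percent),
              x$n_v_cycles))
  if (nrow(x$matches))
    cat(sprintf("  mean optical/voltage duration ratio: %.2f\n",
                mean(x$matches$length_ratio)))
  invisible(x)
}
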