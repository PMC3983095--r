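#' Group a ROI's cycles into episodes
#'
#' An episode is one or more cycles (singlet, doublet, triplet, ...) in a
#' single trace with no return of the fluorescence to baseline between
#' them. Successive cycles are joined into one episode when the minimum
#' intensity between them (from the frame after the earlier cycle's peak
#' to the frame before the next onset — the detected end of a cycle can
#' itself be the next cycle's risen onset frame, so the trough must be
#' sought between the peaks) stays above
#' `onset intensity + baseline_fraction * amplitude` of the episode's
#' first (primary) cycle; otherwise the signal is considered to have
#' returned to baseline and a new episode starts. The 25% default
#' tolerates the slow indicator decay of chemical calcium dyes. Onset
#' intensity is the pre-rise intensity (the frame before the detected
#' onset), consistent with the amplitude convention of
#' [detect_cycles()]: the detected onset frame itself already carries
#' risen fluorescence at 1 Hz.
#'
#' @param recording a [fluorescence_recording()].
#' @param roi ROI identifier.
#' @param cycles cycle data frame for this ROI, sorted and non-overlapping
#'   (as returned by [detect_cycles()]).
#' @param baseline_fraction fraction in (0, 1] of the primary cycle's
#'   amplitude above its onset intensity that counts as "still elevated"
#'   (default 0.25).
#' @return the cycle table with an integer `episode_id` column added
#'   (1-based, per ROI); every cycle belongs to exactly one episode.
#' @seealso [episode_table()]
#' @export
group_episodes <- function(recording, roi, cycles, baseline_fraction = 0.25) {
  stopifnot(baseline_fraction > 0, baseline_fraction <= 1)
  trace <- roi_trace(recording, roi)
  cycles <- validate_cycles(cycles, length(trace))
  if (nrow(cycles) && !all(cycles$roi_id == roi))
    stop("cycles are not all from ROI '", roi, "'")
  cycles <- cycles[order(cycles$onset_frame), , drop = FALSE]
  rownames(cycles) <- NULL
  ep <- integer(nrow(cycles))
  # pre-rise intensity at a 0-based onset frame (the onset frame itself
  # already carries risen fluorescence; see detect_cycles amplitude rule)
  pre_intensity <- function(onset0) {
    i <- onset0 + 1L
    min(trace[max(i - 1L, 1L)], trace[i])
  }
  if (nrow(cycles)) {
    ep[1] <- 1L
    # baseline criterion is anchored to the episode's primary cycle
    prim_onset_int <- pre_intensity(cycles$onset_frame[1])
    prim_amp <- cycles$amplitude[1]
    for (i in seq_len(nrow(cycles))[-1]) {
      lo <- cycles$peak_frame[i - 1] + 1L      # 0-based frame after prev peak
      hi <- cycles$onset_frame[i] - 1L         # pre-rise frame of next cycle
      trough <- if (hi < lo) pre_intensity(cycles$onset_frame[i]) else
        min(trace[(lo:hi) + 1L])
      if (trough > prim_onset_int + baseline_fraction * prim_amp) {
        ep[i] <- ep[i - 1]
      } else {
        ep[i] <- ep[i - 1] + 1L
        prim_onset_int <- pre_intensity(cycles$onset_frame[i])
        prim_amp <- cycles$amplitude[i]
      }
    }
  }
  cycles$episode_id <- ep
  cycles
}

#' Summarise episodes, one row per episode
#'
#' @param cycles cycle data frame carrying an `episode_id` column (from
#'   [group_episodes()]), one or several ROIs.
#' @return data frame with columns `roi_id`, `episode_id`, `n_cycles`,
#'   `onset_frame` (of the primary cycle), `end_frame` (exclusive end of
#'   the last cycle).
#' @export
episode_table <- function(cycles) {
  if (!"episode_id" %in% names(cycles))
    stop("cycles lack an episode_id column; run group_episodes() first")
  if (!nrow(cycles))
    return(data.frame(roi_id = character(), episode_id = integer(),
                      n_cycles = integer(), onset_frame = integer(),
                      end_frame = integer(), stringsAsFactors = FALSE))
  key <- interaction(cycles$roi_id, cycles$episode_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(cycles, key), function(g)
    data.frame(roi_id = g$roi_id[1], episode_id = g$episode_id[1],
               n_cycles = nrow(g), onset_frame = min(g$onset_frame),
               end_frame = max(g$onset_frame + g$duration_frames),
               stringsAsFactors = FALSE)))
  out <- out[order(out$roi_id, out$onset_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-ROI and population activity summary
#'
#' A ROI is active if it has at least one detected cycle. Frequency is
#' cycles per minute over the recording duration; population means are
#' taken over active ROIs only. The percentage of cycles occurring in
#' multi-cycle episodes (doublets and above) is reported when the cycle
#' table carries episode assignments.
#'
#' @param recording a [fluorescence_recording()].
#' @param cycles combined cycle data frame, with or without `episode_id`.
#' @return an object of class `activity_summary`: list with `per_roi`
#'   (data frame: `roi_id`, `active`, `n_cycles`, `frequency_per_min`,
#'   `mean_duration_s`) and `population` (data frame with
#'   `percent_active`, `mean_frequency_per_min`, `mean_duration_s`,
#'   `percent_multi_cycle`, `n_rois`, `n_active`).
#' @export
summarize_activity <- function(recording, cycles) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  cycles <- validate_cycles(cycles, n_frames(recording))
  minutes <- duration_s(recording) / 60
  if (minutes <= 0) stop("zero-length recording")
  per <- data.frame(roi_id = recording$roi_ids, stringsAsFactors = FALSE)
  counts <- table(factor(cycles$roi_id, levels = recording$roi_ids))
  per$n_cycles <- as.integer(counts[per$roi_id])
  per$active <- per$n_cycles > 0L
  per$frequency_per_min <- per$n_cycles / minutes
  frame_s <- 1 / recording$sampling_rate_hz
  mean_dur <- tapply(cycles$duration_frames * frame_s,
                     factor(cycles$roi_id, levels = recording$roi_ids),
                     mean)
  per$mean_duration_s <- as.numeric(mean_dur[per$roi_id])

  pct_multi <- NA_real_
  if ("episode_id" %in% names(cycles) && nrow(cycles)) {
    ep <- episode_table(cycles)
    multi <- ep[ep$n_cycles >= 2L, c("roi_id", "episode_id")]
    in_multi <- interaction(cycles$roi_id, cycles$episode_id) %in%
      interaction(multi$roi_id, multi$episode_id)
    pct_multi <- 100 * sum(in_multi) / nrow(cycles)
  }
  pop <- data.frame(
    n_rois = nrow(per),
    n_active = sum(per$active),
    percent_active = 100 * sum(per$active) / nrow(per),
    mean_frequency_per_min = if (any(per$active))
      mean(per$frequency_per_min[per$active]) else NA_real_,
    mean_duration_s = if (any(per$active))
      mean(per$mean_duration_s[per$active]) else NA_real_,
    percent_multi_cycle = pct_multi)
  structure(list(per_roi = per, population = pop),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  p <- x$population
  cat(sprintf("<activity_summary> %d/%d ROIs active (%.1f%%)\n",
              p$n_active, p$n_rois, p$percent_active))
  if (!is.na(p$mean_frequency_per_min))
    cat(sprintf("  mean frequency (active ROIs): %.2f cycles/min\n",
                p$mean_frequency_per_min))
  if (!is.na(p$mean_duration_s))
    cat(sprintf("  mean cycle duration:          %.2f s\n", p$mean_duration_s))
  if (!is.na(p$percent_multi_cycle))
    cat(sprintf("  cycles in multi-cycle episodes: %.1f%%\n",
                p$percent_multi_cycle))
  invisible(x)
}
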