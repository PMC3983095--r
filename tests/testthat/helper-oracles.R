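# Independent brute-force re-implementations used as oracles. These are
# deliberately written as plain per-frame state machines, sharing no code
# with the package internals.

# derivative-threshold cycle scan: onset at the first frame of each
# maximal supra-threshold run of the differential not covered by an open
# cycle; offset at the first frame where the differential, having gone
# negative, returns to >= 0; open cycles close at the final frame
oracle_scan <- function(trace, sd_mult = 2) {
  n <- length(trace)
  d <- numeric(n)
  for (t in 2:n) d[t] <- trace[t] - trace[t - 1]
  mu <- sum(d) / n
  sg <- sqrt(sum((d - mu)^2) / (n - 1))
  out <- data.frame(onset = integer(), dur = integer())
  if (sg == 0) return(out)
  thr <- mu + sd_mult * sg
  t <- 1
  while (t <= n) {
    is_run_start <- d[t] > thr && (t == 1 || d[t - 1] <= thr)
    if (!is_run_start) { t <- t + 1; next }
    onset <- t
    off <- NA
    went_negative <- FALSE
    u <- onset + 1
    while (u <= n) {
      if (d[u] < 0) went_negative <- TRUE
      else if (went_negative) { off <- u; break }
      u <- u + 1
    }
    if (is.na(off)) off <- n
    if (off <= onset) off <- onset + 1
    out <- rbind(out, data.frame(onset = onset - 1L, dur = off - onset))
    t <- off
  }
  out
}

# textbook Pearson correlation on two numeric vectors
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random test traces: smooth baseline + occasional jumps + noise,
# exercising both signal-bearing and signal-free regimes
random_trace <- function(n = 60) {
  tr <- cumsum(stats::rnorm(n, 0, 0.4)) + 100
  for (k in seq_len(stats::rpois(1, 2))) {
    at <- sample(n - 5, 1)
    amp <- stats::runif(1, 3, 15)
    tr[at:n] <- tr[at:n] + amp * exp(-(seq_len(n - at + 1) - 1) / 3)
  }
  tr
}

# recording wrapper around a single trace
one_roi_recording <- function(trace, rate = 1, id = "a") {
  fluorescence_recording(matrix(trace, dimnames = list(NULL, id)), rate)
}

# raster with hand-placed cycle intervals (frames 0-based, half-open)
make_raster <- function(n_frames, n_rois, intervals) {
  occ <- matrix(0L, n_frames, n_rois,
                dimnames = list(NULL, paste0("r", seq_len(n_rois))))
  for (iv in intervals) occ[(iv$from + 1):(iv$to), iv$roi] <- 1L
  structure(list(occupancy = occ, roi_ids = colnames(occ),
                 sampling_rate_hz = 1), class = "event_raster")
}
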