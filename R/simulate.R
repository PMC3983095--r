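#' Simulation parameters for developing-network activity
#'
#' The generator emulates fields of developing motor neurons imaged at
#' 1 Hz for 10 minutes: neurons fire isolated (asynchronous) calcium
#' events and participate in network-wide events with distance-dependent
#' recruitment around a seed neuron; events carry singlet/doublet/triplet
#' episode structure. Defaults are anchored to the electrophysiology of
#' this preparation: cycles of mean 2.70 s, inter-cycle gaps of about
#' 3.2 s within an episode, about 25 neurons per 400 um field of view,
#' a ~1 s rise to peak fluorescence, and a slower multi-second indicator
#' decay.
#'
#' @param n_neurons neurons in the field (default 25).
#' @param field_size_um width and height of the field (default 400 x 400).
#' @param duration_s recording length in seconds (default 600).
#' @param sampling_rate_hz imaging rate (default 1).
#' @param active_fraction fraction of neurons in the firing pool; the
#'   rest stay silent and never join network events (default 1).
#' @param rate_async_per_min isolated-event rate per active neuron.
#' @param rate_net_per_min network-event rate per field.
#' @param p_participate per-neuron participation probability in a network
#'   event at zero distance from the seed.
#' @param recruit_scale_um Gaussian distance-decay length of recruitment
#'   around the seed neuron (`Inf` = global recruitment).
#' @param p_doublet,p_triplet probabilities that an episode carries a
#'   second / third cycle (`p_doublet + p_triplet <= 1`).
#' @param cycle_duration_mean_s,cycle_duration_sd_s cycle length
#'   distribution (Gaussian, truncated below at 1.2 s so every simulated
#'   cycle outlasts the sub-second depolarisations the voltage detector
#'   must reject; defaults 2.70 and 0.9).
#' @param inter_cycle_gap_s mean within-episode gap between cycle end and
#'   next cycle start (default 3.2 s).
#' @param kernel_rise_s linear rise time of the calcium kernel (default 1).
#' @param kernel_decay_s exponential decay constant of the kernel
#'   (default 1).
#' @param amplitude mean event amplitude in fluorescence units
#'   (default 100, on a baseline of 100).
#' @param noise_sd additive Gaussian noise s.d. per frame (default 5).
#' @param refractory_s optional post-episodic depression: minimum quiet
#'   time enforced after each episode of a neuron (default 0 = off; the
#'   default model handles re-firing only through merged-event exclusion).
#' @param seed RNG seed; all generator randomness derives from it.
#' @param stage optional preset label carried into rendered recordings.
#' @return an object of class `simulation_params`.
#' @seealso [stage_preset()], [simulate_events()], [render_calcium()]
#' @export
simulation_params <- function(n_neurons = 25L, field_size_um = c(400, 400),
                              duration_s = 600, sampling_rate_hz = 1,
                              active_fraction = 1,
                              rate_async_per_min = 1.0,
                              rate_net_per_min = 0,
                              p_participate = 0.85,
                              recruit_scale_um = Inf,
                              p_doublet = 0, p_triplet = 0,
                              cycle_duration_mean_s = 2.70,
                              cycle_duration_sd_s = 0.9,
                              inter_cycle_gap_s = 3.2,
                              kernel_rise_s = 1, kernel_decay_s = 1,
                              amplitude = 100, noise_sd = 5,
                              refractory_s = 0,
                              seed = 1L, stage = NA_character_) {
  stopifnot(n_neurons >= 1, length(field_size_um) == 2, all(field_size_um > 0),
            duration_s > 0, sampling_rate_hz > 0,
            active_fraction >= 0, active_fraction <= 1,
            rate_async_per_min >= 0, rate_net_per_min >= 0,
            p_participate >= 0, p_participate <= 1, recruit_scale_um > 0,
            p_doublet >= 0, p_triplet >= 0, p_doublet + p_triplet <= 1,
            cycle_duration_mean_s > 0, cycle_duration_sd_s >= 0,
            inter_cycle_gap_s > 0, kernel_rise_s > 0, kernel_decay_s > 0,
            amplitude > 0, noise_sd >= 0, refractory_s >= 0)
  structure(as.list(environment()), class = "simulation_params")
}

#' Developmental-stage presets for the simulator
#'
#' Parameter sets implementing the qualitative developmental progression
#' of this circuit: activity is sparse, asynchronous and confined to few
#' neurons at HH St. 23, network events appear with local recruitment by
#' HH St. 26, dominate with wide recruitment by HH St. 28, and by HH
#' St. 30 most neurons are active, recruitment is effectively global and
#' episodes frequently carry doublet/triplet cycles. Simulating the four
#' presets and running the analysis pipeline reproduces, in direction,
#' the developmental rise of the active fraction, mean pairwise
#' correlation and synchronous-cycle share.
#'
#' @param name one of `"HH23"`, `"HH25"`, `"HH26"`, `"HH28"`, `"HH30"`.
#' @param ... overrides passed on to [simulation_params()] (e.g. `seed`).
#' @return a `simulation_params` object.
#' @export
stage_preset <- function(name, ...) {
  presets <- list(
    HH23 = list(active_fraction = 0.20, rate_async_per_min = 1.45,
                rate_net_per_min = 0, p_participate = 0.30,
                recruit_scale_um = 80, p_doublet = 0.05, p_triplet = 0),
    HH25 = list(active_fraction = 0.30, rate_async_per_min = 1.40,
                rate_net_per_min = 0.05, p_participate = 0.45,
                recruit_scale_um = 120, p_doublet = 0.05, p_triplet = 0),
    HH26 = list(active_fraction = 0.45, rate_async_per_min = 0.90,
                rate_net_per_min = 0.25, p_participate = 0.80,
                recruit_scale_um = 250, p_doublet = 0.08, p_triplet = 0.02),
    HH28 = list(active_fraction = 0.65, rate_async_per_min = 0.35,
                rate_net_per_min = 0.45, p_participate = 0.85,
                recruit_scale_um = 400, p_doublet = 0.15, p_triplet = 0.05),
    HH30 = list(active_fraction = 0.82, rate_async_per_min = 0.12,
                rate_net_per_min = 0.40, p_participate = 0.85,
                recruit_scale_um = Inf, p_doublet = 0.45, p_triplet = 0.35))
  if (!name %in% names(presets))
    stop("unknown stage preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  args <- c(presets[[name]], list(stage = name), list(...))
  do.call(simulation_params, args)
}

neuron_roi_id <- function(i) sprintf("n%02d", i)

# draw one episode template: cycle start offsets (s, relative to the
# episode onset) and durations
draw_episode <- function(params) {
  u <- stats::runif(1)
  n_cyc <- if (u < params$p_triplet) 3L
  else if (u < params$p_triplet + params$p_doublet) 2L
  else 1L
  dur <- pmax(1.2, stats::rnorm(n_cyc, params$cycle_duration_mean_s,
                                params$cycle_duration_sd_s))
  # within-episode gaps floored at 1.5 s: the measured gap distribution
  # (about 3.2 +/- 0.3 s) has no sub-1.5 s mass, and at 1 Hz imaging a
  # shorter gap is unresolvable anyway
  gap <- pmax(1.5, stats::rnorm(max(0L, n_cyc - 1L), params$inter_cycle_gap_s,
                                params$inter_cycle_gap_s / 4))
  start <- cumsum(c(0, if (n_cyc > 1L) dur[-n_cyc] + gap))
  list(start = start, duration = dur)
}

#' Simulate ground-truthed network activity
#'
#' Neuron positions are uniform on the field. Each neuron in the firing
#' pool fires isolated events as a Poisson process at
#' `rate_async_per_min`; network events arrive as a field-wide Poisson
#' process at `rate_net_per_min`, each seeded at a uniformly chosen
#' firing-pool neuron which always participates; every other firing-pool
#' neuron joins with probability
#' `p_participate * exp(-d(i, seed)^2 / (2 * recruit_scale_um^2))`.
#' Every event instantiates an episode of 1-3 cycles (probabilities
#' `p_doublet`, `p_triplet`); network-event participants share the
#' episode template, so their cycles overlap in time. Overlapping cycles
#' on one neuron are merged (union of intervals); with `refractory_s > 0`
#' events starting within that time of the neuron's previous episode end
#' are dropped instead.
#'
#' @param params a [simulation_params()].
#' @return an object of class `ground_truth`: list with `events` (data
#'   frame `neuron`, `roi_id`, `start_s`, `duration_s`, `episode_id`,
#'   `cycle_index`, `network_event_id`), `network_events` (data frame
#'   `id`, `time_s`, `seed_neuron`, `n_participants` plus list-column
#'   `participants`), `positions`, `firing_pool` (neuron indices able to
#'   fire) and `params`.
#' @export
simulate_events <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_neurons
  minutes <- params$duration_s / 60
  positions <- data.frame(
    roi_id = neuron_roi_id(seq_len(n)),
    x_um = stats::runif(n, 0, params$field_size_um[1]),
    y_um = stats::runif(n, 0, params$field_size_um[2]),
    stringsAsFactors = FALSE)
  pool <- which(stats::runif(n) < params$active_fraction)

  ev <- list()
  episode_counter <- 0L
  add_episode <- function(neuron, t0, tmpl, net_id) {
    episode_counter <<- episode_counter + 1L
    keep <- t0 + tmpl$start < params$duration_s
    if (!any(keep)) return(NULL)
    data.frame(neuron = neuron,
               start_s = t0 + tmpl$start[keep],
               duration_s = pmin(tmpl$duration[keep],
                                 params$duration_s - (t0 + tmpl$start[keep])),
               episode_id = episode_counter,
               cycle_index = seq_len(sum(keep)),
               network_event_id = net_id,
               stringsAsFactors = FALSE)
  }

  # isolated (asynchronous) events
  for (i in pool) {
    k <- stats::rpois(1, params$rate_async_per_min * minutes)
    if (!k) next
    for (t0 in sort(stats::runif(k, 0, params$duration_s)))
      ev[[length(ev) + 1L]] <- add_episode(i, t0, draw_episode(params), NA_integer_)
  }

  # network events with distance-dependent recruitment
  n_net <- stats::rpois(1, params$rate_net_per_min * minutes)
  net <- data.frame(id = integer(), time_s = double(), seed_neuron = integer(),
                    n_participants = integer())
  net_participants <- list()
  if (n_net > 0L && length(pool)) {
    times <- sort(stats::runif(n_net, 0, params$duration_s))
    for (e in seq_len(n_net)) {
      seed_n <- pool[sample.int(length(pool), 1L)]
      d2 <- (positions$x_um[pool] - positions$x_um[seed_n])^2 +
        (positions$y_um[pool] - positions$y_um[seed_n])^2
      p_join <- params$p_participate * exp(-d2 / (2 * params$recruit_scale_um^2))
      join <- pool[stats::runif(length(pool)) < p_join]
      join <- union(seed_n, join)      # the seed initiates its own event
      tmpl <- draw_episode(params)
      for (i in join)
        ev[[length(ev) + 1L]] <- add_episode(i, times[e], tmpl, e)
      net <- rbind(net, data.frame(id = e, time_s = times[e],
                                   seed_neuron = seed_n,
                                   n_participants = length(join)))
      net_participants[[e]] <- sort(join)
    }
  }
  net$participants <- net_participants

  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(neuron = integer(), start_s = double(),
                         duration_s = double(), episode_id = integer(),
                         cycle_index = integer(),
                         network_event_id = integer())
  events <- merge_neuron_events(events, params$refractory_s)
  events$roi_id <- neuron_roi_id(events$neuron)
  events <- events[order(events$neuron, events$start_s),
                   c("neuron", "roi_id", "start_s", "duration_s",
                     "episode_id", "cycle_index", "network_event_id")]
  rownames(events) <- NULL
  structure(list(events = events, network_events = net,
                 positions = positions, firing_pool = pool, params = params),
            class = "ground_truth")
}

# merge per-neuron cycles that overlap or fall within min_gap_s of each
# other (union of intervals, metadata of the earlier cycle): a neuron
# cannot fire two independent cycle onsets within a couple of seconds,
# and sub-gap events are unresolvable at the imaging rate. With a
# refractory period, later episodes starting within refractory_s of the
# previous episode's end are dropped instead.
merge_neuron_events <- function(events, refractory_s = 0, min_gap_s = 2) {
  if (!nrow(events)) return(events)
  out <- lapply(split(events, events$neuron), function(g) {
    g <- g[order(g$start_s), , drop = FALSE]
    keep <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      last <- nrow(keep)
      last_end <- keep$start_s[last] + keep$duration_s[last]
      if (refractory_s > 0 && g$episode_id[i] != keep$episode_id[last] &&
          g$start_s[i] < last_end + refractory_s) next
      same_episode <- g$episode_id[i] == keep$episode_id[last]
      if (g$start_s[i] < last_end + (if (same_episode) 0 else min_gap_s)) {
        new_end <- max(last_end, g$start_s[i] + g$duration_s[i])
        keep$duration_s[last] <- new_end - keep$start_s[last]
      } else {
        keep <- rbind(keep, g[i, , drop = FALSE])
      }
    }
    keep
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d neurons (%d firing), %d cycles, %d network events, %g s\n",
    x$params$n_neurons, length(x$firing_pool), nrow(x$events),
    nrow(x$network_events), x$params$duration_s))
  invisible(x)
}

# calcium impulse response: linear rise to `amplitude` over rise_s, then
# exponential decay truncated to exactly zero below 0.5% of amplitude so
# the differential of a noise-free trace returns to zero in finite time
calcium_kernel <- function(x, amplitude, rise_s, decay_s) {
  y <- numeric(length(x))
  up <- x >= 0 & x < rise_s
  y[up] <- amplitude * x[up] / rise_s
  down <- x >= rise_s
  y[down] <- amplitude * exp(-(x[down] - rise_s) / decay_s)
  y[y < 0.005 * amplitude] <- 0
  y
}

#' Render a simulated field as a fluorescence recording
#'
#' Each ground-truth cycle contributes a calcium kernel (linear rise over
#' `kernel_rise_s` to `amplitude`, exponential decay with constant
#' `kernel_decay_s`, truncated to zero below 0.5% of amplitude);
#' contributions sum on a baseline of 100 a.u., and i.i.d. Gaussian noise
#' of `noise_sd` is added to every frame of every neuron. Rendering is
#' seeded from `params$seed` (offset so the event draw and the noise draw
#' are independent), so identical truth gives identical frames.
#'
#' @param truth a `ground_truth` from [simulate_events()].
#' @return a [fluorescence_recording()] carrying the simulated positions
#'   and the preset's stage label.
#' @export
render_calcium <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  params <- truth$params
  set.seed(params$seed + 1L)
  n_fr <- as.integer(round(params$duration_s * params$sampling_rate_hz))
  tt <- (seq_len(n_fr) - 1L) / params$sampling_rate_hz
  frames <- matrix(100, n_fr, params$n_neurons,
                   dimnames = list(NULL, neuron_roi_id(seq_len(params$n_neurons))))
  tail_s <- params$kernel_rise_s + params$kernel_decay_s * log(200)
  for (i in seq_len(nrow(truth$events))) {
    e <- truth$events[i, ]
    a <- max(1L, ceiling(e$start_s * params$sampling_rate_hz))
    b <- min(n_fr, 1L + floor((e$start_s + tail_s) * params$sampling_rate_hz))
    if (a > b) next
    idx <- a:b
    frames[idx, e$neuron] <- frames[idx, e$neuron] +
      calcium_kernel(tt[idx] - e$start_s, params$amplitude,
                     params$kernel_rise_s, params$kernel_decay_s)
  }
  if (params$noise_sd > 0)
    frames <- frames + matrix(stats::rnorm(length(frames), 0, params$noise_sd),
                              nrow(frames))
  fluorescence_recording(frames, params$sampling_rate_hz,
                         positions = truth$positions,
                         stage_label = params$stage)
}

#' Render a paired voltage trace for one simulated neuron
#'
#' Each true cycle of the neuron becomes a +25 mV depolarisation plateau
#' of the cycle's duration on a -48.8 mV baseline with 1 mV Gaussian
#' noise, sampled at 1 kHz. Additional sub-second (+10 mV, 0.2-0.9 s)
#' depolarisations are injected at `n_subthreshold_per_min`; these have
#' no calcium counterpart and must never be matched by
#' [match_events()].
#'
#' @param truth a `ground_truth` from [simulate_events()].
#' @param neuron neuron index (1-based) within the simulated field.
#' @param n_subthreshold_per_min rate of sub-second depolarisations
#'   (default 2 per minute).
#' @param rate_hz voltage sampling rate (default 1000).
#' @return a [voltage_trace()] with attributes `cycle_events` (the
#'   neuron's true cycles) and `subthreshold_events` (data frame
#'   `start_s`, `duration_s`).
#' @export
render_voltage <- function(truth, neuron, n_subthreshold_per_min = 2,
                           rate_hz = 1000) {
  stopifnot(inherits(truth, "ground_truth"),
            neuron >= 1, neuron <= truth$params$n_neurons)
  params <- truth$params
  set.seed(params$seed + 1000L + as.integer(neuron))
  n <- as.integer(round(params$duration_s * rate_hz))
  vm <- stats::rnorm(n, -48.8, 1)
  cyc <- truth$events[truth$events$neuron == neuron, , drop = FALSE]
  for (i in seq_len(nrow(cyc))) {
    a <- max(1L, 1L + as.integer(round(cyc$start_s[i] * rate_hz)))
    b <- min(n, as.integer(round((cyc$start_s[i] + cyc$duration_s[i]) * rate_hz)))
    if (a <= b) vm[a:b] <- vm[a:b] + 25
  }
  k <- stats::rpois(1, n_subthreshold_per_min * params$duration_s / 60)
  sub <- data.frame(start_s = double(), duration_s = double())
  if (k > 0) {
    sub <- data.frame(start_s = sort(stats::runif(k, 0, params$duration_s - 1)),
                      duration_s = stats::runif(k, 0.2, 0.9))
    for (i in seq_len(k)) {
      a <- max(1L, 1L + as.integer(round(sub$start_s[i] * rate_hz)))
      b <- min(n, as.integer(round((sub$start_s[i] + sub$duration_s[i]) * rate_hz)))
      if (a <= b) vm[a:b] <- vm[a:b] + 10
    }
  }
  out <- voltage_trace(vm, rate_hz)
  attr(out, "cycle_events") <- cyc
  attr(out, "subthreshold_events") <- sub
  out
}

#' Score detected cycles against simulator ground truth
#'
#' Greedy one-to-one matching of detected onsets to true event onsets
#' (converted to frames by rounding) within `tol_frames`. Recall is the
#' fraction of true events with a matching detection; precision the
#' fraction of detections matching a true event.
#'
#' @param truth a `ground_truth`.
#' @param cycles detected cycle data frame (roi ids as rendered, frames
#'   0-based).
#' @param tol_frames matching tolerance in frames (default 1).
#' @return list with `recall`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`, and the per-ROI match table `by_roi`.
#' @export
score_detection <- function(truth, cycles, tol_frames = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  cycles <- validate_cycles(cycles)
  rate <- truth$params$sampling_rate_hz
  rois <- union(unique(truth$events$roi_id), unique(cycles$roi_id))
  rows <- lapply(rois, function(r) {
    true_on <- sort(round(truth$events$start_s[truth$events$roi_id == r] * rate))
    det_on <- sort(cycles$onset_frame[cycles$roi_id == r])
    used <- rep(FALSE, length(det_on))
    m <- 0L
    for (o in true_on) {
      cand <- which(!used & abs(det_on - o) <= tol_frames)
      if (length(cand)) { used[cand[1]] <- TRUE; m <- m + 1L }
    }
    data.frame(roi_id = r, n_true = length(true_on),
               n_detected = length(det_on), n_matched = m,
               stringsAsFactors = FALSE)
  })
  by_roi <- do.call(rbind, rows)
  n_true <- sum(by_roi$n_true)
  n_det <- sum(by_roi$n_detected)
  n_m <- sum(by_roi$n_matched)
  list(recall = if (n_true) n_m / n_true else NA_real_,
       precision = if (n_det) n_m / n_det else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_m,
       by_roi = by_roi)
}
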