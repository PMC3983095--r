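test_that("simulation is bit-identical under a fixed seed", {
  p <- stage_preset("HH28", seed = 123)
  t1 <- simulate_events(p)
  t2 <- simulate_events(p)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$positions, t2$positions)
  expect_identical(render_calcium(t1)$frames, render_calcium(t2)$frames)
  v1 <- render_voltage(t1, 1)
  v2 <- render_voltage(t2, 1)
  expect_identical(v1$vm_mv, v2$vm_mv)
})

test_that("zero rates give an empty ground truth", {
  p <- simulation_params(rate_async_per_min = 0, rate_net_per_min = 0, seed = 4)
  truth <- simulate_events(p)
  expect_equal(nrow(truth$events), 0L)
  expect_equal(nrow(truth$network_events), 0L)
})

test_that("global recruitment with certain participation includes everyone", {
  p <- simulation_params(n_neurons = 12, rate_async_per_min = 0,
                         rate_net_per_min = 0.5, p_participate = 1,
                         recruit_scale_um = Inf, seed = 10)
  truth <- simulate_events(p)
  expect_gt(nrow(truth$network_events), 0L)
  expect_true(all(truth$network_events$n_participants == 12L))
})

test_that("events stay inside the recording and never overlap per neuron", {
  p <- stage_preset("HH30", seed = 55)
  truth <- simulate_events(p)
  ev <- truth$events
  expect_true(all(ev$start_s >= 0))
  expect_true(all(ev$start_s + ev$duration_s <= p$duration_s + 1e-9))
  for (nr in unique(ev$neuron)) {
    g <- ev[ev$neuron == nr, ]
    g <- g[order(g$start_s), ]
    if (nrow(g) > 1)
      expect_true(all(g$start_s[-1] >= (g$start_s + g$duration_s)[-nrow(g)] - 1e-9))
  }
  # participant sets consistent with per-neuron event lists
  for (i in seq_len(nrow(truth$network_events))) {
    who <- truth$network_events$participants[[i]]
    id <- truth$network_events$id[i]
    listed <- unique(ev$neuron[!is.na(ev$network_event_id) &
                                 ev$network_event_id == id])
    expect_true(all(listed %in% who))
  }
})

test_that("per-neuron event counts follow the Poisson expectation", {
  # expected episodes per neuron = duration * (r_async + r_net * P(join)),
  # with P(join) = p + (1 - p)/n for the uniformly chosen seed neuron
  n <- 5
  p_join <- 0.5 + (1 - 0.5) / n
  expect_rate <- 10 * (0.2 + 0.1 * p_join)
  counts <- integer(0)
  for (s in 1:50) {
    p <- simulation_params(n_neurons = n, active_fraction = 1,
                           rate_async_per_min = 0.2, rate_net_per_min = 0.1,
                           p_participate = 0.5, recruit_scale_um = Inf,
                           seed = 7000 + s)
    truth <- simulate_events(p)
    counts <- c(counts, vapply(seq_len(n), function(i)
      length(unique(truth$events$episode_id[truth$events$neuron == i])),
      integer(1)))
  }
  total <- sum(counts)
  expected <- length(counts) * expect_rate
  se <- sqrt(expected)
  expect_lt(abs(total - expected), 3 * se + 0.03 * expected)  # 3 SE + merge loss
})

test_that("the calcium kernel renders rise, peak and clean baseline", {
  p <- simulation_params(n_neurons = 2, rate_async_per_min = 0,
                         rate_net_per_min = 0, noise_sd = 0, seed = 2)
  truth <- simulate_events(p)
  rec <- render_calcium(truth)
  expect_true(all(rec$frames == 100))     # no events, no noise -> flat

  truth$events <- data.frame(neuron = 1L, roi_id = "n01", start_s = 50,
                             duration_s = 2.7, episode_id = 1L,
                             cycle_index = 1L, network_event_id = NA_integer_)
  rec1 <- render_calcium(truth)
  tr <- rec1$frames[, "n01"]
  expect_equal(max(tr), 100 + p$amplitude)       # peak at rise completion
  expect_equal(which.max(tr), 52L)               # onset 50 s -> peak frame 51 (0-based)
  expect_equal(tr[45], 100)                      # pre-event baseline
  expect_equal(tail(tr, 1), 100)                 # decay truncates to baseline
  expect_true(all(rec1$frames[, "n02"] == 100))
})

test_that("rendered voltage carries plateau cycles and sub-second extras", {
  p <- simulation_params(n_neurons = 2, rate_async_per_min = 0, seed = 3,
                         duration_s = 120)
  truth <- simulate_events(p)
  truth$events <- data.frame(neuron = 1L, roi_id = "n01", start_s = 60,
                             duration_s = 2.7, episode_id = 1L,
                             cycle_index = 1L, network_event_id = NA_integer_)
  vt <- render_voltage(truth, 1, n_subthreshold_per_min = 0)
  above <- vt$vm_mv > -48.8 + 15
  expect_equal(sum(above), 2700, tolerance = 1)
  r <- rle(above)
  expect_equal(sum(r$values), 1L)                # one contiguous plateau

  vt2 <- render_voltage(truth, 1, n_subthreshold_per_min = 5)
  sub <- attr(vt2, "subthreshold_events")
  expect_gt(nrow(sub), 0L)
  expect_true(all(sub$duration_s < 1))
  # sub-second bumps are +10 mV: visible above baseline but below plateau
  mid <- round(sub$start_s[1] * 1000 + sub$duration_s[1] * 500)
  expect_gt(vt2$vm_mv[mid], -45)
})

test_that("detector recovers noise-free rendered events exactly", {
  p <- stage_preset("HH26", noise_sd = 0, seed = 11)
  truth <- simulate_events(p)
  rec <- render_calcium(truth)
  cyc <- suppressWarnings(detect_cycles(rec))
  sc <- score_detection(truth, cyc, tol_frames = 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("stage presets encode the developmental progression", {
  expect_error(stage_preset("HH99"), "unknown")
  hh23 <- stage_preset("HH23")
  expect_equal(hh23$rate_net_per_min, 0)
  expect_lt(hh23$p_participate, 0.5)
  expect_lt(hh23$active_fraction, 0.3)
  hh30 <- stage_preset("HH30")
  expect_gt(hh30$p_doublet + hh30$p_triplet, 0)
  expect_gt(hh30$active_fraction, 0.8)
  expect_true(is.infinite(hh30$recruit_scale_um))
  fracs <- vapply(c("HH23", "HH26", "HH28", "HH30"),
                  function(s) stage_preset(s)$active_fraction, double(1))
  expect_true(all(diff(fracs) > 0))
})
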