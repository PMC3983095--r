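test_that("differentiate matches hand arithmetic and keeps length", {
  expect_equal(differentiate(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  expect_equal(differentiate(c(0, 1, 3, 6)), c(0, 1, 2, 3))
  expect_error(differentiate(c(1, 2), smooth_window_frames = 3), "shorter")
  expect_error(differentiate(1:10, smooth_window_frames = 2), "odd")
})

test_that("smoothed differential equals a direct moving-average oracle", {
  withr::with_seed(5, tr <- rnorm(50, 100, 10))
  # independent computation: truncated centred window, then difference
  sm <- vapply(seq_along(tr), function(i) {
    idx <- max(1, i - 1):min(length(tr), i + 1)
    mean(tr[idx])
  }, double(1))
  expect_equal(differentiate(tr, 3), c(0, diff(sm)))
})

test_that("a flat trace yields no cycles, with a warning", {
  rec <- one_roi_recording(rep(100, 600))
  expect_warning(cyc <- detect_cycles(rec), "zero-variance")
  expect_equal(nrow(cyc), 0L)
})

test_that("the 16-point worked trace yields one cycle with the scanned bounds", {
  tr <- c(10, 10, 10, 10, 18, 24, 24, 22, 20, 18, 16, 14, 12, 11, 11, 11)
  cyc <- detect_cycles(one_roi_recording(tr))
  # differential: 0,0,0,0,8,6,0,-2*6,-1,0,0 -> threshold crossed at frame 4;
  # differential goes negative at frame 7 and first returns to >= 0 at frame 14
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$onset_frame, 4L)
  expect_equal(cyc$duration_frames, 10L)
  expect_equal(cyc$peak_frame, 5L)
  expect_equal(cyc$amplitude, 14)     # peak 24 minus pre-rise 10
})

test_that("detector matches the brute-force scan oracle on random traces", {
  withr::with_seed(42, {
    n_mismatch <- 0
    for (i in 1:120) {
      tr <- random_trace(60)
      rec <- one_roi_recording(tr)
      got <- suppressWarnings(detect_cycles(rec))
      want <- oracle_scan(tr)
      same <- identical(got$onset_frame, as.integer(want$onset)) &&
        identical(got$duration_frames, as.integer(want$dur))
      if (!same) n_mismatch <- n_mismatch + 1
    }
    expect_equal(n_mismatch, 0)
  })
})

test_that("detection is covariant under affine rescaling of the trace", {
  withr::with_seed(9, {
    for (i in 1:20) {
      tr <- random_trace(80)
      a <- runif(1, 0.1, 50)
      b <- runif(1, -100, 100)
      c1 <- suppressWarnings(detect_cycles(one_roi_recording(tr)))
      c2 <- suppressWarnings(detect_cycles(one_roi_recording(a * tr + b)))
      expect_equal(c2$onset_frame, c1$onset_frame)
      expect_equal(c2$duration_frames, c1$duration_frames)
      expect_equal(c2$peak_frame, c1$peak_frame)
    }
  })
})

test_that("identical inputs give identical cycle tables", {
  withr::with_seed(3, tr <- random_trace(100))
  rec <- one_roi_recording(tr)
  expect_identical(suppressWarnings(detect_cycles(rec)),
                   suppressWarnings(detect_cycles(rec)))
})

test_that("min_duration drops short cycles and merge_gap fuses neighbours", {
  # two clean transients three frames apart
  tr <- rep(100, 40)
  tr[11:14] <- c(150, 135, 120, 108)
  tr[18:21] <- c(150, 135, 120, 108)
  rec <- one_roi_recording(tr)
  base <- detect_cycles(rec)
  expect_equal(nrow(base), 2L)
  gap <- base$onset_frame[2] - (base$onset_frame[1] + base$duration_frames[1])
  merged <- detect_cycles(rec, detection_params(merge_gap_frames = gap + 1))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$onset_frame, base$onset_frame[1])
  expect_equal(merged$duration_frames,
               base$onset_frame[2] + base$duration_frames[2] -
                 base$onset_frame[1])
  none <- detect_cycles(rec, detection_params(min_duration_frames = 100))
  expect_equal(nrow(none), 0L)
})

test_that("SNR is amplitude over out-of-cycle spread, with degenerate flags", {
  tr <- rep(c(98, 102), 25)              # out-of-cycle sd = sd(+-2) pattern
  tr[21:24] <- c(120, 115, 108, 104)
  rec <- one_roi_recording(tr)
  cyc <- data.frame(roi_id = "a", onset_frame = 20L, duration_frames = 4L,
                    peak_frame = 20L, amplitude = 10,
                    snr = NA_real_, sync_label = "unclassified")
  out_sd <- sd(tr[-(21:24)])
  expect_equal(compute_snr(rec, "a", cyc), 10 / out_sd)

  # noise-free baseline -> infinite SNR flag, not an error
  tr2 <- rep(100, 30); tr2[11:13] <- c(140, 120, 105)
  cyc2 <- data.frame(roi_id = "a", onset_frame = 10L, duration_frames = 3L,
                     peak_frame = 10L, amplitude = 40,
                     snr = NA_real_, sync_label = "unclassified")
  expect_equal(compute_snr(one_roi_recording(tr2), "a", cyc2), Inf)

  # cycles covering the whole trace -> undefined
  cyc3 <- data.frame(roi_id = "a", onset_frame = 0L, duration_frames = 30L,
                     peak_frame = 10L, amplitude = 40,
                     snr = NA_real_, sync_label = "unclassified")
  expect_true(is.na(compute_snr(one_roi_recording(tr2), "a", cyc3)))
})

test_that("reported SNR tracks the generator's amplitude-to-noise ratio", {
  p <- simulation_params(n_neurons = 6, rate_async_per_min = 0.8,
                         amplitude = 100, noise_sd = 10, seed = 77)
  truth <- simulate_events(p)
  rec <- render_calcium(truth)
  cyc <- suppressWarnings(detect_cycles(rec))
  cyc <- annotate_snr(rec, cyc)
  cyc <- filter_cycles_snr(rec, cyc, 6)
  # the sampled peak underestimates the continuous amplitude by up to
  # ~20% when the onset falls mid-frame, so the mean reported SNR sits
  # slightly below nominal amplitude/noise
  nominal <- p$amplitude / p$noise_sd
  expect_gt(mean(cyc$snr), 0.75 * nominal)
  expect_lt(mean(cyc$snr), 1.15 * nominal)
})

test_that("raster occupancy counts equal summed cycle durations", {
  rec <- fluorescence_recording(matrix(100, 600, 3,
                                       dimnames = list(NULL, c("a", "b", "c"))), 1)
  cyc <- data.frame(roi_id = c("a", "a", "c"),
                    onset_frame = c(4L, 100L, 0L),
                    duration_frames = c(10L, 7L, 600L),
                    peak_frame = c(5L, 101L, 3L),
                    amplitude = 1, snr = NA_real_,
                    sync_label = "unclassified")
  ras <- build_raster(rec, cyc)
  expect_equal(unname(colSums(ras$occupancy)), c(17, 0, 600))
  expect_equal(sum(ras$occupancy[5:14, "a"]), 10)

  empty <- build_raster(rec, empty_cycles())
  expect_true(all(empty$occupancy == 0L))

  overlap <- rbind(cyc, data.frame(roi_id = "a", onset_frame = 8L,
                                   duration_frames = 3L, peak_frame = 8L,
                                   amplitude = 1, snr = NA_real_,
                                   sync_label = "unclassified"))
  expect_error(build_raster(rec, overlap), "overlap")
})

test_that("raster column sums match per-ROI durations on random cycle sets", {
  withr::with_seed(11, {
    rec <- fluorescence_recording(matrix(100, 200, 4), 1)
    for (rep in 1:10) {
      cyc <- empty_cycles()
      for (r in rec$roi_ids) {
        pos <- 0L
        while (pos < 180L && runif(1) < 0.7) {
          on <- pos + sample(1:20, 1)
          du <- sample(1:10, 1)
          if (on + du > 200) break
          cyc <- rbind(cyc, data.frame(roi_id = r, onset_frame = on,
                                       duration_frames = du,
                                       peak_frame = on, amplitude = 1,
                                       snr = NA_real_,
                                       sync_label = "unclassified"))
          pos <- on + du
        }
      }
      ras <- build_raster(rec, cyc)
      want <- tapply(cyc$duration_frames,
                     factor(cyc$roi_id, levels = rec$roi_ids), sum)
      want[is.na(want)] <- 0
      expect_equal(unname(colSums(ras$occupancy)), unname(as.numeric(want)))
    }
  })
})
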