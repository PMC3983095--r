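test_that("participation fractions and the strict 60% rule classify events", {
  # one lone cycle in one of five ROIs: one event, fraction 0.2, asynchronous
  r1 <- make_raster(30, 5, list(list(roi = 1, from = 5, to = 10)))
  ev1 <- find_network_events(r1)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$participation_fraction, 0.2)
  expect_false(ev1$synchronous)

  # overlapping cycles in 4 of 5 -> 0.8 > 0.6 -> synchronous
  r4 <- make_raster(30, 5, lapply(1:4, function(i)
    list(roi = i, from = 5, to = 12)))
  ev4 <- find_network_events(r4)
  expect_equal(ev4$participation_fraction, 0.8)
  expect_true(ev4$synchronous)

  # exactly 3 of 5 (fraction 0.6) stays asynchronous: strict inequality
  r3 <- make_raster(30, 5, lapply(1:3, function(i)
    list(roi = i, from = 5, to = 12)))
  ev3 <- find_network_events(r3)
  expect_equal(ev3$participation_fraction, 0.6)
  expect_false(ev3$synchronous)
})

test_that("chained overlaps form one event; disjoint cycles form several", {
  ras <- make_raster(40, 3, list(
    list(roi = 1, from = 0, to = 6),
    list(roi = 2, from = 4, to = 12),    # overlaps roi 1
    list(roi = 3, from = 10, to = 15),   # overlaps roi 2, not roi 1
    list(roi = 1, from = 30, to = 33)))  # far away
  ev <- find_network_events(ras)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_participants, c(3L, 1L))
  expect_equal(ev$start_frame, c(0L, 30L))
  expect_equal(ev$end_frame, c(15L, 33L))

  # adjacent half-open intervals share no frame: two events
  ras2 <- make_raster(20, 2, list(list(roi = 1, from = 0, to = 5),
                                  list(roi = 2, from = 5, to = 9)))
  expect_equal(nrow(find_network_events(ras2)), 2L)
})

test_that("active denominator only increases fractions", {
  ras <- make_raster(30, 6, lapply(1:3, function(i)
    list(roi = i, from = 2, to = 9)))
  lab <- find_network_events(ras, denominator = "labelled")
  act <- find_network_events(ras, denominator = "active")
  expect_equal(lab$participation_fraction, 0.5)
  expect_equal(act$participation_fraction, 1)
  expect_gte(act$participation_fraction, lab$participation_fraction)
})

test_that("coactive participation distinguishes chains from true co-firing", {
  # four ROIs chained A-B-C-D but never more than two up at once
  chain <- make_raster(40, 4, list(
    list(roi = 1, from = 0, to = 6),
    list(roi = 2, from = 5, to = 12),
    list(roi = 3, from = 11, to = 18),
    list(roi = 4, from = 17, to = 24)))
  ev_o <- find_network_events(chain, denominator = "active")
  ev_c <- find_network_events(chain, denominator = "active",
                              participation = "coactive")
  expect_equal(ev_o$n_participants, 4L)
  expect_true(ev_o$synchronous)            # 4/4 by overlap closure
  expect_equal(ev_c$peak_coactive, 2L)
  expect_false(ev_c$synchronous)           # at most 2/4 = 0.5 co-active

  # genuinely simultaneous cycles stay synchronous under both conventions
  co <- make_raster(40, 4, lapply(1:4, function(i)
    list(roi = i, from = 5, to = 12)))
  expect_true(find_network_events(co, denominator = "active")$synchronous)
  expect_true(find_network_events(co, denominator = "active",
                                  participation = "coactive")$synchronous)
})

test_that("a lone active neuron is never synchronous", {
  ras <- make_raster(30, 5, list(list(roi = 2, from = 3, to = 9)))
  ev <- find_network_events(ras, denominator = "active")
  expect_equal(ev$participation_fraction, 1)
  expect_false(ev$synchronous)
  ev_c <- find_network_events(ras, denominator = "active",
                              participation = "coactive")
  expect_false(ev_c$synchronous)
})

test_that("cycles inherit the synchrony flag of their containing event", {
  rec <- fluorescence_recording(
    matrix(100, 40, 5, dimnames = list(NULL, paste0("r", 1:5))), 1)
  cyc <- rbind(
    data.frame(roi_id = paste0("r", 1:4), onset_frame = c(5L, 6L, 7L, 5L),
               duration_frames = 6L, peak_frame = c(6L, 7L, 8L, 6L),
               amplitude = 10, snr = NA_real_, sync_label = "unclassified"),
    data.frame(roi_id = "r5", onset_frame = 25L, duration_frames = 3L,
               peak_frame = 25L, amplitude = 10, snr = NA_real_,
               sync_label = "unclassified"))
  ras <- build_raster(rec, cyc)
  ev <- find_network_events(ras)
  lab <- label_cycles(cyc, ev)
  expect_equal(lab$sync_label,
               c(rep("synchronous", 4), "asynchronous"))
  expect_false(any(lab$sync_label == "unclassified"))

  # events from a different raster cannot label these cycles
  expect_error(label_cycles(cyc, ev[ev$start_frame > 20, , drop = FALSE]),
               "no network event")
})

test_that("correlation matrix equals textbook Pearson and flags degeneracy", {
  ras <- make_raster(30, 3, list(
    list(roi = 1, from = 2, to = 10),
    list(roi = 2, from = 2, to = 10),      # identical to roi 1
    list(roi = 3, from = 15, to = 25)))    # disjoint in time
  res <- correlation_matrix(ras)
  expect_equal(res$matrix["r1", "r2"], 1)
  expect_equal(res$matrix["r1", "r3"],
               oracle_pearson(ras$occupancy[, 1], ras$occupancy[, 3]))
  expect_lt(res$matrix["r1", "r3"], 0)     # complementary occupancy
  expect_true(isSymmetric(res$matrix))

  # an all-zero column is invalid, not silently zero
  ras0 <- make_raster(30, 3, list(list(roi = 1, from = 2, to = 10),
                                  list(roi = 2, from = 4, to = 12)))
  res0 <- correlation_matrix(ras0)
  expect_true(is.na(res0$matrix["r1", "r3"]))
  expect_false(res0$valid["r1", "r3"])
  expect_equal(res0$per_roi_mean[["r1"]], res0$matrix["r1", "r2"])
  expect_true(is.na(res0$per_roi_mean[["r3"]]))

  expect_error(correlation_matrix(make_raster(10, 1, list())), "2 ROIs")
})

test_that("correlation matches brute-force Pearson on random rasters", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      occ <- matrix(rbinom(20 * 4, 1, 0.3), 20, 4,
                    dimnames = list(NULL, paste0("r", 1:4)))
      ras <- structure(list(occupancy = occ, roi_ids = colnames(occ),
                            sampling_rate_hz = 1), class = "event_raster")
      res <- correlation_matrix(ras)
      for (i in 1:3) for (j in (i + 1):4) {
        if (sd(occ[, i]) == 0 || sd(occ[, j]) == 0) {
          expect_true(is.na(res$matrix[i, j]))
        } else {
          expect_equal(res$matrix[i, j], oracle_pearson(occ[, i], occ[, j]),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("synchrony-split statistics report per-class rates and flag absence", {
  rec <- fluorescence_recording(
    matrix(100, 600, 3, dimnames = list(NULL, c("a", "b", "c"))), 1)
  cyc <- data.frame(roi_id = "a", onset_frame = seq(0L, 540L, by = 60L),
                    duration_frames = 3L, peak_frame = seq(0L, 540L, by = 60L),
                    amplitude = 10, snr = NA_real_,
                    sync_label = "asynchronous")
  s <- synchrony_split_stats(cyc, rec)
  as_row <- s[s$sync_label == "asynchronous", ]
  expect_equal(as_row$frequency_per_min, 1.0)
  expect_equal(as_row$mean_duration_s, 3)
  sy_row <- s[s$sync_label == "synchronous", ]
  expect_false(sy_row$present)
  expect_true(is.na(sy_row$frequency_per_min))

  expect_error(synchrony_split_stats(
    transform(cyc, sync_label = "unclassified"), rec), "labelled")
})

test_that("distance-correlation histogram bins pairs and normalises to 100", {
  ras <- make_raster(30, 2, list(list(roi = 1, from = 2, to = 10),
                                 list(roi = 2, from = 2, to = 10)))
  res <- correlation_matrix(ras)
  pos <- data.frame(roi_id = c("r1", "r2"), x_um = c(0, 100), y_um = c(0, 0))
  h <- distance_correlation_histogram(res, pos)
  expect_equal(h$n_pairs, 1L)
  expect_equal(sum(h$percent), 100)
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$pairs$distance_um, 100)
  expect_equal(h$pairs$coefficient, 1)
  # the single pair lands in the top correlation bin
  expect_equal(h$counts[, ncol(h$counts)][which(h$counts[, ncol(h$counts)] > 0)], 1L)

  expect_error(distance_correlation_histogram(res, NULL), "required")
})

test_that("histogram pair count is bounded by n(n-1)/2 and percent sums to 100", {
  withr::with_seed(23, {
    p <- stage_preset("HH28", seed = 404)
    truth <- simulate_events(p)
    a <- analyze_recording(render_calcium(truth))
    h <- distance_correlation_histogram(a$correlation, truth$positions)
    n <- length(a$correlation$roi_ids)
    expect_lte(h$n_pairs, n * (n - 1) / 2)
    expect_equal(sum(h$percent), 100)
    expect_equal(sum(h$counts), h$n_pairs)
  })
})

test_that("detected synchrony agrees with generator network-event labels", {
  p <- simulation_params(n_neurons = 25, rate_async_per_min = 0.3,
                         rate_net_per_min = 0.5, p_participate = 0.9,
                         recruit_scale_um = Inf, seed = 88)
  truth <- simulate_events(p)
  a <- analyze_recording(render_calcium(truth))
  cyc <- a$cycles
  # truth-side synchrony: cycle belongs to a network event recruiting
  # more than 60% of the 25 labelled neurons
  big <- truth$network_events$id[
    truth$network_events$n_participants > 0.6 * p$n_neurons]
  agree <- 0L
  for (i in seq_len(nrow(cyc))) {
    tr_ev <- truth$events[truth$events$roi_id == cyc$roi_id[i] &
                            abs(round(truth$events$start_s) -
                                  cyc$onset_frame[i]) <= 2, ]
    if (!nrow(tr_ev)) next
    want <- !is.na(tr_ev$network_event_id[1]) &&
      tr_ev$network_event_id[1] %in% big
    got <- cyc$sync_label[i] == "synchronous"
    agree <- agree + as.integer(want == got)
  }
  expect_gte(agree / nrow(cyc), 0.95)
})
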