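#' Pipeline configuration
#'
#' Bundles the inputs and parameters of a full analysis run:
#' detect cycles -> SNR -> episodes -> raster -> network events ->
#' synchrony labels -> correlations (-> distance histogram when ROI
#' positions are available).
#'
#' @param trace_path fluorescence trace table (header = ROI ids).
#' @param out_dir output directory; created if missing.
#' @param sampling_rate_hz imaging rate (default 1).
#' @param positions_path optional ROI centroid table.
#' @param detection a [detection_params()].
#' @param snr_min discard cycles with SNR below this before any
#'   population statistic (default 6; see [filter_cycles_snr()]). Set 0
#'   to keep raw detections.
#' @param baseline_fraction episode-grouping threshold (default 0.25).
#' @param sync_threshold synchrony participation threshold (default 0.6).
#' @param sync_denominator `"labelled"` or `"active"`.
#' @param corr_mode `"binary"` or `"raw"`.
#' @param distance_bins,correlation_bins histogram binning (see
#'   [distance_correlation_histogram()]).
#' @param seed seed recorded in output headers (the core pipeline is
#'   deterministic; the seed matters when the config is used to simulate).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(trace_path, out_dir, sampling_rate_hz = 1,
                            positions_path = NULL,
                            detection = detection_params(),
                            snr_min = 6,
                            baseline_fraction = 0.25,
                            sync_threshold = 0.6,
                            sync_denominator = "labelled",
                            corr_mode = "binary",
                            distance_bins = 10, correlation_bins = 10,
                            seed = 1L) {
  stopifnot(inherits(detection, "detection_params"))
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[setdiff(names(config), "out_dir")], tf)
  unname(tools::md5sum(tf))
}

output_header <- function(config, hash) {
  c(sprintf("# motorsync %s",
            as.character(utils::packageVersion("motorsync"))),
    sprintf("# config_hash=%s seed=%d", hash, as.integer(config$seed)))
}

write_output <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes detection, episode grouping, synchrony analysis and
#' correlation on one recording, and writes `cycles.csv`,
#' `network_events.csv`, `correlation_matrix.csv`, `per_roi.csv`,
#' `population.csv`, `sync_split.csv`, `distance_correlation.csv` (when
#' positions are available) and `manifest.txt` into the output
#' directory. Every output file starts with comment lines recording the
#' package version, a hash of the configuration and the seed, so a rerun
#' with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the computed objects (`recording`,
#'   `cycles`, `events`, `correlation`, `summary`, `split`, `histogram`)
#'   and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$trace_path, config$positions_path))
    if (!file.exists(p)) stop("input file missing: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  header <- output_header(config, hash)

  rec <- read_recording(config$trace_path, config$sampling_rate_hz,
                        positions_path = config$positions_path)
  cycles <- detect_cycles(rec, config$detection)
  cycles <- annotate_snr(rec, cycles)
  cycles <- filter_cycles_snr(rec, cycles, config$snr_min)
  grouped <- lapply(unique(cycles$roi_id), function(r)
    group_episodes(rec, r, cycles[cycles$roi_id == r, , drop = FALSE],
                   config$baseline_fraction))
  if (length(grouped)) {
    cycles <- do.call(rbind, grouped)
  } else {
    cycles <- empty_cycles()
    cycles$episode_id <- integer(0)
  }
  raster <- build_raster(rec, cycles)
  events <- find_network_events(raster, config$sync_threshold,
                                config$sync_denominator)
  cycles <- label_cycles(cycles, events)
  corr <- correlation_matrix(raster, mode = config$corr_mode, recording = rec)
  summ <- summarize_activity(rec, cycles)
  split_stats <- synchrony_split_stats(cycles, rec)

  paths <- list(
    cycles = file.path(config$out_dir, "cycles.csv"),
    network_events = file.path(config$out_dir, "network_events.csv"),
    correlation = file.path(config$out_dir, "correlation_matrix.csv"),
    per_roi = file.path(config$out_dir, "per_roi.csv"),
    population = file.path(config$out_dir, "population.csv"),
    sync_split = file.path(config$out_dir, "sync_split.csv"),
    manifest = file.path(config$out_dir, "manifest.txt"))

  ord <- order(cycles$roi_id, cycles$onset_frame)
  write_output(cycles[ord, , drop = FALSE], paths$cycles, header)
  ev_flat <- events[, c("start_frame", "end_frame", "n_participants",
                        "participation_fraction", "synchronous")]
  write_output(ev_flat, paths$network_events, header)
  cm <- data.frame(roi_id = corr$roi_ids, round(corr$matrix, 6),
                   check.names = FALSE)
  write_output(cm, paths$correlation, header)
  per_roi <- summ$per_roi
  per_roi$mean_correlation <- round(corr$per_roi_mean[per_roi$roi_id], 6)
  write_output(per_roi, paths$per_roi, header)
  write_output(summ$population, paths$population, header)
  write_output(split_stats, paths$sync_split, header)

  hist_obj <- NULL
  if (!is.null(rec$positions)) {
    hist_obj <- distance_correlation_histogram(
      corr, rec$positions, config$distance_bins, config$correlation_bins)
    hdf <- as.data.frame(as.table(hist_obj$percent))
    names(hdf) <- c("distance_bin", "correlation_bin", "percent")
    hdf$percent <- round(hdf$percent, 6)
    paths$distance_correlation <-
      file.path(config$out_dir, "distance_correlation.csv")
    write_output(hdf, paths$distance_correlation, header)
  }

  manifest <- c(header,
                sprintf("trace_path=%s", config$trace_path),
                sprintf("positions_path=%s",
                        config$positions_path %||% "(none)"),
                sprintf("sampling_rate_hz=%g", config$sampling_rate_hz),
                sprintf("sd_multiplier=%g", config$detection$sd_multiplier),
                sprintf("smooth_window_frames=%d",
                        config$detection$smooth_window_frames),
                sprintf("min_duration_frames=%d",
                        config$detection$min_duration_frames),
                sprintf("merge_gap_frames=%d",
                        config$detection$merge_gap_frames),
                sprintf("snr_min=%g", config$snr_min),
                sprintf("baseline_fraction=%g", config$baseline_fraction),
                sprintf("sync_threshold=%g", config$sync_threshold),
                sprintf("sync_denominator=%s", config$sync_denominator),
                sprintf("corr_mode=%s", config$corr_mode),
                sprintf("seed=%d", as.integer(config$seed)))
  writeLines(manifest, paths$manifest)

  invisible(list(recording = rec, cycles = cycles, events = events,
                 correlation = corr, summary = summ, split = split_stats,
                 histogram = hist_obj, paths = paths))
}

#' Analyse a recording in memory
#'
#' Runs the core analysis chain — detection, SNR annotation and
#' filtering, episode grouping, raster construction, network-event
#' classification, synchrony labelling, correlation and activity
#' summaries — on a [fluorescence_recording()], without touching the
#' file system. [run_pipeline()] is the file-based counterpart.
#'
#' @param recording a [fluorescence_recording()].
#' @param detection a [detection_params()].
#' @param snr_min SNR filter threshold (see [filter_cycles_snr()]).
#' @param baseline_fraction episode-grouping threshold.
#' @param sync_threshold,sync_denominator,sync_participation see
#'   [find_network_events()]. Developmental-stage comparisons should use
#'   the `"active"` denominator (when fewer than 60% of labelled neurons
#'   are active at all, no cycle can be synchronous under the
#'   `"labelled"` convention) together with `"coactive"` participation
#'   (chance chains of long transients otherwise masquerade as synchrony
#'   in sparsely active fields).
#' @param corr_mode `"binary"` or `"raw"` (see [correlation_matrix()]).
#' @return list with `cycles` (labelled, episode-annotated), `raster`,
#'   `events`, `correlation`, `summary`, `split`, and convenience scalars
#'   `mean_pairwise_correlation` (mean over valid upper-triangle pairs),
#'   `percent_active` and `percent_synchronous` (share of cycles
#'   labelled synchronous; `NA` with no cycles).
#' @export
analyze_recording <- function(recording, detection = detection_params(),
                              snr_min = 6, baseline_fraction = 0.25,
                              sync_threshold = 0.6,
                              sync_denominator = "labelled",
                              sync_participation = "overlap",
                              corr_mode = "binary") {
  cycles <- suppressWarnings(detect_cycles(recording, detection))
  cycles <- annotate_snr(recording, cycles)
  cycles <- filter_cycles_snr(recording, cycles, snr_min)
  grouped <- lapply(unique(cycles$roi_id), function(r)
    group_episodes(recording, r, cycles[cycles$roi_id == r, , drop = FALSE],
                   baseline_fraction))
  if (length(grouped)) {
    cycles <- do.call(rbind, grouped)
  } else {
    cycles <- empty_cycles()
    cycles$episode_id <- integer(0)
  }
  raster <- build_raster(recording, cycles)
  events <- find_network_events(raster, sync_threshold, sync_denominator,
                                sync_participation)
  cycles <- label_cycles(cycles, events)
  corr <- correlation_matrix(raster, mode = corr_mode, recording = recording)
  summ <- summarize_activity(recording, cycles)
  split_stats <- synchrony_split_stats(cycles, recording)
  v <- corr$matrix[upper.tri(corr$matrix)]
  list(cycles = cycles, raster = raster, events = events,
       correlation = corr, summary = summ, split = split_stats,
       mean_pairwise_correlation =
         if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
       percent_active = summ$population$percent_active,
       percent_synchronous =
         if (nrow(cycles)) 100 * mean(cycles$sync_label == "synchronous")
         else NA_real_)
}

#' Simulate a preset and write its trace, positions and ground truth
#'
#' Convenience wrapper used by the command-line `simulate` subcommand.
#'
#' @param params a [simulation_params()] (e.g. from [stage_preset()]).
#' @param out_dir output directory.
#' @param voltage_neuron optional neuron index; when given, a paired
#'   voltage trace for that neuron is also written.
#' @return invisibly, list of written paths.
#' @export
simulate_to_dir <- function(params, out_dir, voltage_neuron = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_events(params)
  rec <- render_calcium(truth)
  paths <- list(trace = file.path(out_dir, "trace.csv"),
                positions = file.path(out_dir, "positions.csv"),
                truth = file.path(out_dir, "ground_truth.csv"))
  write_recording(rec, paths$trace, paths$positions)
  utils::write.csv(truth$events, paths$truth, row.names = FALSE, quote = FALSE)
  if (!is.null(voltage_neuron)) {
    vt <- render_voltage(truth, voltage_neuron)
    paths$voltage <- file.path(out_dir, "voltage.csv")
    write_voltage(vt, paths$voltage)
  }
  invisible(paths)
}
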