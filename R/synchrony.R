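#' Find network events in an event raster
#'
#' A network event is a maximal set of temporally overlapping cycles
#' across ROIs ("occurred simultaneously" is operationalised as interval
#' overlap with transitive closure, not onset coincidence: at 1 Hz
#' sampling exact onset equality is fragile). Occupied frames are grouped
#' into connected components of overlapping cycle intervals; each
#' component yields one event spanning `[start_frame, end_frame)` with
#' the set of participating ROIs. An event is synchronous when its
#' participation fraction is strictly greater than `sync_threshold`
#' (the ">60% of labelled neurons" rule).
#'
#' @param raster an `event_raster` from [build_raster()].
#' @param sync_threshold participation fraction above which an event is
#'   synchronous (default 0.6, strict inequality).
#' @param denominator `"labelled"` (default) counts all raster columns;
#'   `"active"` counts only ROIs with at least one occupied frame.
#'   Switching to `"active"` can only increase fractions.
#' @param participation `"overlap"` (default) counts every ROI whose
#'   cycle belongs to the event's transitive overlap closure;
#'   `"coactive"` classifies synchrony by the event's peak instantaneous
#'   co-activity (the largest number of ROIs occupied in any single
#'   frame of the event). Chained overlaps of long calcium transients
#'   can span most of a small active set by chance, so co-activity is
#'   the appropriate criterion when few neurons are active (early
#'   developmental stages); both conventions coincide for genuinely
#'   simultaneous network events.
#' @return data frame with one row per event: `start_frame`, `end_frame`
#'   (half-open, 0-based), `n_participants`, `participation_fraction`,
#'   `peak_coactive`, `peak_coactive_fraction`, `synchronous`, and a
#'   list-column `participants` of ROI id vectors. With the default
#'   `participation = "overlap"`, `synchronous` is exactly
#'   `participation_fraction > sync_threshold`; with `"coactive"` it is
#'   `peak_coactive_fraction > sync_threshold`.
#' @export
find_network_events <- function(raster, sync_threshold = 0.6,
                                denominator = c("labelled", "active"),
                                participation = c("overlap", "coactive")) {
  stopifnot(inherits(raster, "event_raster"),
            sync_threshold > 0, sync_threshold < 1)
  denominator <- match.arg(denominator)
  participation <- match.arg(participation)
  occ <- raster$occupancy
  n_total <- switch(denominator,
                    labelled = ncol(occ),
                    active = max(1L, sum(colSums(occ) > 0L)))
  # reconstruct cycle intervals per column, then component-split by overlap
  ivals <- do.call(rbind, lapply(seq_len(ncol(occ)), function(j) {
    r <- rle(occ[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values == 1L)
    if (!length(k)) return(NULL)
    data.frame(roi = raster$roi_ids[j], start = starts[k], end = ends[k] + 1L)
  }))
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      n_participants = integer(),
                      participation_fraction = double(),
                      peak_coactive = integer(),
                      peak_coactive_fraction = double(),
                      synchronous = logical())
  empty$participants <- list()
  if (is.null(ivals) || !nrow(ivals)) return(empty)
  ivals <- ivals[order(ivals$start, ivals$end), , drop = FALSE]
  comp <- integer(nrow(ivals))
  comp[1] <- 1L
  reach <- ivals$end[1]
  for (i in seq_len(nrow(ivals))[-1]) {
    if (ivals$start[i] < reach) {          # shares >= 1 frame with component
      comp[i] <- comp[i - 1]
      reach <- max(reach, ivals$end[i])
    } else {
      comp[i] <- comp[i - 1] + 1L
      reach <- ivals$end[i]
    }
  }
  coactive <- rowSums(occ)
  out <- do.call(rbind, lapply(split(ivals, comp), function(g) {
    n_p <- length(unique(g$roi))
    peak <- max(coactive[min(g$start):(max(g$end) - 1L)])
    data.frame(start_frame = min(g$start) - 1L,     # to 0-based
               end_frame = max(g$end) - 1L,
               n_participants = n_p,
               participation_fraction = n_p / n_total,
               peak_coactive = as.integer(peak),
               peak_coactive_fraction = peak / n_total,
               # a lone cycle is not simultaneous with anything: synchrony
               # additionally requires at least two co-occurring neurons
               # (guards the degenerate 1-active-ROI field under the
               # "active" denominator)
               synchronous = switch(participation,
                                    overlap = n_p / n_total,
                                    coactive = peak / n_total) > sync_threshold &
                 switch(participation, overlap = n_p, coactive = peak) >= 2L)
  }))
  out$participants <- lapply(split(ivals, comp), function(g) unique(g$roi))
  rownames(out) <- NULL
  out
}

#' Label cycles synchronous or asynchronous
#'
#' Every cycle inherits the synchrony flag of the network event containing
#' its onset frame. Cycles and events must come from the same raster; a
#' cycle whose onset falls in no event indicates an internal inconsistency
#' and raises an error.
#'
#' @param cycles cycle data frame.
#' @param events event table from [find_network_events()].
#' @return the cycle table with `sync_label` set to `"synchronous"` or
#'   `"asynchronous"` on every row.
#' @export
label_cycles <- function(cycles, events) {
  cycles <- validate_cycles(cycles)
  if (!nrow(cycles)) return(cycles)
  idx <- vapply(cycles$onset_frame, function(o) {
    k <- which(events$start_frame <= o & o < events$end_frame)
    if (!length(k)) NA_integer_ else k[1]
  }, integer(1))
  if (anyNA(idx))
    stop("cycle onset at frame ",
         cycles$onset_frame[which(is.na(idx))[1]],
         " matches no network event; cycles and events are inconsistent")
  cycles$sync_label <- ifelse(events$synchronous[idx],
                              "synchronous", "asynchronous")
  cycles
}

#' Pairwise correlation of ROI activity
#'
#' Pearson correlation between the activity time series of every ROI
#' pair. By default the binary occupancy series are correlated
#' ("correlation of firing"); `mode = "raw"` instead correlates the raw
#' fluorescence traces of the recording. Pairs where either series has
#' zero variance (e.g. an inactive ROI's all-zero occupancy) have no
#' defined coefficient; they are flagged invalid, never silently 0, and
#' excluded from per-ROI means.
#'
#' @param raster an `event_raster` with >= 2 ROIs.
#' @param mode `"binary"` (default) or `"raw"`.
#' @param recording required when `mode = "raw"`: the matching
#'   [fluorescence_recording()].
#' @return an object of class `correlation_result`: list with `matrix`
#'   (symmetric, unit diagonal for valid ROIs, `NA` on invalid entries),
#'   `valid` (logical matrix of defined pairs), `per_roi_mean` (mean of
#'   each ROI's valid off-diagonal coefficients) and `roi_ids`.
#' @export
correlation_matrix <- function(raster, mode = c("binary", "raw"),
                               recording = NULL) {
  stopifnot(inherits(raster, "event_raster"))
  mode <- match.arg(mode)
  x <- switch(mode,
              binary = raster$occupancy,
              raw = {
                if (is.null(recording))
                  stop("mode = 'raw' needs the recording")
                stopifnot(identical(recording$roi_ids, raster$roi_ids))
                recording$frames
              })
  if (ncol(x) < 2L) stop("correlation needs at least 2 ROIs")
  sds <- apply(x, 2, stats::sd)
  ok <- sds > 0
  m <- matrix(NA_real_, ncol(x), ncol(x),
              dimnames = list(raster$roi_ids, raster$roi_ids))
  if (sum(ok) >= 2L)
    m[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  diag(m)[ok] <- 1
  valid <- !is.na(m)
  per_roi <- vapply(seq_len(ncol(m)), function(i) {
    v <- m[i, -i]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, double(1))
  names(per_roi) <- raster$roi_ids
  structure(list(matrix = m, valid = valid, per_roi_mean = per_roi,
                 roi_ids = raster$roi_ids),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  v <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "<correlation_result> %d ROIs, %d/%d valid pairs, mean coefficient %.3f\n",
    length(x$roi_ids), sum(!is.na(v)), length(v),
    mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Frequency and duration statistics split by synchrony class
#'
#' For each class (synchronous / asynchronous), frequency is computed per
#' ROI active in that class (cycles per minute) and then averaged, and
#' mean cycle duration is reported in seconds. A class with no cycles is
#' reported as absent (`NA` rows, `present = FALSE`), never as zero.
#'
#' @param cycles labelled cycle data frame (all rows classified).
#' @param recording the recording the cycles came from (supplies duration
#'   and sampling rate).
#' @return data frame with one row per class: `sync_label`, `present`,
#'   `n_cycles`, `n_rois`, `frequency_per_min`, `mean_duration_s`.
#' @export
synchrony_split_stats <- function(cycles, recording) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  cycles <- validate_cycles(cycles, n_frames(recording))
  if (nrow(cycles) && any(cycles$sync_label == "unclassified"))
    stop("all cycles must be labelled; run label_cycles() first")
  minutes <- duration_s(recording) / 60
  frame_s <- 1 / recording$sampling_rate_hz
  out <- lapply(c("synchronous", "asynchronous"), function(cl) {
    g <- cycles[cycles$sync_label == cl, , drop = FALSE]
    if (!nrow(g))
      return(data.frame(sync_label = cl, present = FALSE, n_cycles = 0L,
                        n_rois = 0L, frequency_per_min = NA_real_,
                        mean_duration_s = NA_real_, stringsAsFactors = FALSE))
    per_roi <- table(g$roi_id) / minutes
    data.frame(sync_label = cl, present = TRUE, n_cycles = nrow(g),
               n_rois = length(per_roi),
               frequency_per_min = mean(per_roi),
               mean_duration_s = mean(g$duration_frames * frame_s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-dimensional distance-correlation histogram
#'
#' For every valid unordered ROI pair, the Euclidean distance between
#' centroids (x axis) and the pair's correlation coefficient (y axis) are
#' binned; counts are normalised to percentages over all valid pairs
#' ("pixel intensity indicates the percentage of interactions"). By
#' default distance uses 10 equal bins spanning the observed range and
#' correlation 10 bins over [0, 1], with negative coefficients clamped
#' into the lowest bin.
#'
#' @param result a `correlation_result` from [correlation_matrix()].
#' @param positions data frame `roi_id`, `x_um`, `y_um` covering every ROI.
#' @param distance_bins number of distance bins, or a vector of monotone
#'   bin edges in micrometres.
#' @param correlation_bins number of correlation bins over [0, 1], or a
#'   vector of monotone edges.
#' @return an object of class `distance_correlation_histogram`: list with
#'   `counts` and `percent` matrices (distance bins x correlation bins),
#'   `distance_bin_edges`, `correlation_bin_edges`, `n_pairs`, and the
#'   per-pair table `pairs` (`roi_a`, `roi_b`, `distance_um`,
#'   `coefficient`).
#' @export
distance_correlation_histogram <- function(result, positions,
                                           distance_bins = 10,
                                           correlation_bins = 10) {
  stopifnot(inherits(result, "correlation_result"))
  if (is.null(positions)) stop("positions are required")
  positions <- validate_positions(positions, result$roi_ids)
  n <- length(result$roi_ids)
  pr <- which(upper.tri(result$matrix), arr.ind = TRUE)
  coef <- result$matrix[pr]
  keep <- !is.na(coef)
  pr <- pr[keep, , drop = FALSE]
  coef <- coef[keep]
  d <- sqrt((positions$x_um[pr[, 1]] - positions$x_um[pr[, 2]])^2 +
              (positions$y_um[pr[, 1]] - positions$y_um[pr[, 2]])^2)
  pairs <- data.frame(roi_a = result$roi_ids[pr[, 1]],
                      roi_b = result$roi_ids[pr[, 2]],
                      distance_um = d, coefficient = coef,
                      stringsAsFactors = FALSE)
  if (length(distance_bins) == 1L) {
    rng <- if (length(d)) range(d) else c(0, 1)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    d_edges <- seq(rng[1], rng[2], length.out = distance_bins + 1L)
  } else d_edges <- distance_bins
  if (length(correlation_bins) == 1L)
    c_edges <- seq(0, 1, length.out = correlation_bins + 1L)
  else c_edges <- correlation_bins
  if (is.unsorted(d_edges, strictly = TRUE) ||
      is.unsorted(c_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  di <- findInterval(d, d_edges, rightmost.closed = TRUE, all.inside = TRUE)
  # negative coefficients clamp into the lowest correlation bin
  ci <- findInterval(pmax(coef, c_edges[1]), c_edges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(d_edges) - 1L, length(c_edges) - 1L)
  for (i in seq_along(di)) counts[di[i], ci[i]] <- counts[di[i], ci[i]] + 1L
  percent <- if (length(di)) 100 * counts / length(di) else counts * 0
  structure(list(counts = counts, percent = percent,
                 distance_bin_edges = d_edges,
                 correlation_bin_edges = c_edges,
                 n_pairs = length(di), pairs = pairs),
            class = "distance_correlation_histogram")
}

#' @export
print.distance_correlation_histogram <- function(x, ...) {
  cat(sprintf(
    "<distance_correlation_histogram> %d valid pairs, %d x %d bins\n",
    x$n_pairs, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
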