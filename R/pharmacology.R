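#' Baseline-normalised comparison of an activity metric between conditions
#'
#' Reproduces the structure of drug-application tables: each neuron's
#' metric value (cycle frequency in cycles/min, or cycle length in
#' seconds) is divided by the mean baseline value of the embryo it came
#' from, so the baseline group mean is exactly 1 by construction, and the
#' normalised treatment group is compared against the normalised baseline
#' group with a two-sided test. Normalisation is per embryo, then values
#' are pooled across embryos, matching table `n`s given in neurons.
#'
#' Embryos whose baseline epoch has no cycles (zero baseline mean) cannot
#' be normalised; their treatment neurons are excluded with a warning.
#'
#' @param baseline,treatment data frames with columns `embryo` and
#'   `value`, one row per neuron (or per cycle for length data). Every
#'   embryo appearing in `treatment` must also appear in `baseline`.
#' @param metric label stored on the result: `"frequency"` or `"length"`.
#' @param test `"mannwhitney"` (default; the normalised ratios are not
#'   normal and group sizes differ) or `"welch"`.
#' @return an object of class `condition_comparison`: list with `metric`,
#'   `test_name`, `n_baseline`, `n_treatment`, `mean_baseline` (always 1
#'   when defined), `mean_normalized`, `sem_baseline`, `sem_treatment`,
#'   `p_value`, and the pooled per-neuron table `normalized`.
#' @examples
#' base <- data.frame(embryo = rep(1:2, each = 5), value = rep(c(2, 4), each = 5))
#' trt <- data.frame(embryo = rep(1:2, each = 5), value = rep(c(1, 2), each = 5))
#' normalize_and_compare(base, trt)   # mean_normalized 0.5
#' @export
normalize_and_compare <- function(baseline, treatment,
                                  metric = c("frequency", "length"),
                                  test = c("mannwhitney", "welch")) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  baseline <- as.data.frame(baseline)
  treatment <- as.data.frame(treatment)
  for (nm in list(baseline, treatment))
    if (!all(c("embryo", "value") %in% names(nm)))
      stop("baseline and treatment need columns 'embryo' and 'value'")
  if (!nrow(baseline)) stop("empty baseline group")
  missing <- setdiff(unique(treatment$embryo), unique(baseline$embryo))
  if (length(missing))
    stop("treatment embryo(s) without a baseline epoch: ",
         paste(missing, collapse = ", "))

  base_mean <- tapply(baseline$value, baseline$embryo, mean)
  dead <- names(base_mean)[base_mean == 0]
  if (length(dead)) {
    warning("embryo(s) with zero baseline mean excluded: ",
            paste(dead, collapse = ", "))
    baseline <- baseline[!baseline$embryo %in% dead, , drop = FALSE]
    treatment <- treatment[!treatment$embryo %in% dead, , drop = FALSE]
    if (!nrow(baseline)) stop("no embryos with non-zero baseline remain")
  }
  norm_b <- baseline$value / base_mean[as.character(baseline$embryo)]
  norm_t <- if (nrow(treatment))
    treatment$value / base_mean[as.character(treatment$embryo)] else double(0)

  p <- NA_real_
  if (length(norm_t)) {
    if (stats::sd(c(norm_b, norm_t)) == 0) {
      p <- 1  # both groups constant and equal; no test statistic defined
    } else if (test == "mannwhitney") {
      p <- suppressWarnings(
        stats::wilcox.test(norm_t, norm_b, exact = FALSE)$p.value)
    } else if (stats::sd(norm_b) == 0 && stats::sd(norm_t) == 0) {
      p <- 0  # two distinct constants: complete separation, Welch undefined
    } else {
      p <- stats::t.test(norm_t, norm_b)$p.value
    }
  }
  pooled <- rbind(
    data.frame(group = "baseline", embryo = baseline$embryo,
               value_normalized = as.numeric(norm_b)),
    if (nrow(treatment))
      data.frame(group = "treatment", embryo = treatment$embryo,
                 value_normalized = as.numeric(norm_t)))
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(
    metric = metric,
    test_name = switch(test, mannwhitney = "Mann-Whitney rank test",
                       welch = "Welch two-sample t test"),
    n_baseline = length(norm_b), n_treatment = length(norm_t),
    mean_baseline = mean(norm_b),
    mean_normalized = if (length(norm_t)) mean(norm_t) else NA_real_,
    sem_baseline = sem(norm_b), sem_treatment = sem(norm_t),
    p_value = p, normalized = pooled),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> metric: %s, %s\n", x$metric, x$test_name))
  cat(sprintf("  baseline : n = %d, mean = %.3f (SEM %.3f)\n",
              x$n_baseline, x$mean_baseline, x$sem_baseline))
  cat(sprintf("  treatment: n = %d, mean = %.4f (SEM %s)\n",
              x$n_treatment, x$mean_normalized,
              if (is.na(x$sem_treatment)) "NA" else sprintf("%.3f", x$sem_treatment)))
  cat(sprintf("  P = %s\n", format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Per-neuron cycle frequency or length by embryo
#'
#' Helper assembling the input of [normalize_and_compare()] from detected
#' cycle tables: one recording per embryo and epoch.
#'
#' @param recordings named list of [fluorescence_recording()]s, one per
#'   embryo (names are embryo ids).
#' @param cycles_list list of cycle data frames parallel to `recordings`.
#' @param metric `"frequency"` (cycles/min per neuron; inactive neurons
#'   contribute 0) or `"length"` (per-cycle duration in seconds).
#' @return data frame with columns `embryo` and `value`.
#' @export
per_neuron_metric <- function(recordings, cycles_list,
                              metric = c("frequency", "length")) {
  metric <- match.arg(metric)
  stopifnot(length(recordings) == length(cycles_list),
            !is.null(names(recordings)))
  out <- mapply(function(embryo, rec, cyc) {
    cyc <- validate_cycles(cyc, n_frames(rec))
    if (metric == "frequency") {
      minutes <- duration_s(rec) / 60
      counts <- table(factor(cyc$roi_id, levels = rec$roi_ids))
      data.frame(embryo = embryo, value = as.numeric(counts) / minutes,
                 stringsAsFactors = FALSE)
    } else {
      if (!nrow(cyc)) return(NULL)
      data.frame(embryo = embryo,
                 value = cyc$duration_frames / rec$sampling_rate_hz,
                 stringsAsFactors = FALSE)
    }
  }, names(recordings), recordings, cycles_list, SIMPLIFY = FALSE)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
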