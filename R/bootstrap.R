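#' @title Patient-level bootstrap inference
#' @name bootstrap_inference
#' @description
#' Repeated measures within a patient are handled by resampling whole
#' patients: each replicate draws N patients with replacement from the N in
#' the cohort, recomputes the metric on the resampled cohort (duplicated
#' patients contribute duplicated events and points), and the standard
#' error is the standard deviation of the replicate metrics. Confidence
#' intervals are normal-approximation (estimate +/- z * se) by default.
NULL

# deterministic per-replicate substream seed below 2^31
substream_seed <- function(seed, i) {
  m <- 2147483647
  x <- ((as.double(seed) %% m) * 48271 + as.double(i) * 104729) %% m
  as.integer(x) + 1L
}

#' Bootstrap a per-patient-unit statistic
#'
#' Generic engine: `units` is a list with one element per patient (records,
#' labeled-point subsets, scalars, ...) and `stat` maps a list of units to
#' a number. Replicates where `stat` returns `NA` (e.g. a resample with no
#' positives) are dropped and counted; more than 50% undefined replicates
#' is an error.
#'
#' @param units List of per-patient units (the exchangeable resampling
#'   unit).
#' @param stat Function: list of units -> single number (may be `NA`).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Master seed; each replicate uses a deterministic substream.
#' @return List with `replicates` (length `n_reps`, `NA` where undefined),
#'   `se`, `n_dropped`.
#' @export
bootstrap_patient_stat <- function(units, stat, n_reps = 2000, seed = 1) {
  n <- length(units)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  reps <- vapply(seq_len(n_reps), function(r) {
    set.seed(substream_seed(seed, r))
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(stat(units[idx]), error = function(e) NA_real_)
    if (is.null(v) || length(v) != 1L || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  n_dropped <- sum(is.na(reps))
  if (n_dropped > n_reps / 2) {
    stop("metric undefined on more than half the bootstrap replicates (",
         n_dropped, "/", n_reps, "); not bootstrappable on this cohort",
         call. = FALSE)
  }
  list(replicates = reps, se = stats::sd(reps, na.rm = TRUE),
       n_dropped = n_dropped)
}

#' Patient-level bootstrap of a cohort metric
#'
#' @param cohort A [hemo_cohort] data frame.
#' @param metric Function: cohort -> single number. Resampled cohorts carry
#'   disambiguated patient ids (`id.1`, `id.2`, ...) so a patient drawn
#'   twice contributes twice.
#' @param n_reps Number of replicates (2000 by default).
#' @param seed Master seed.
#' @param ci_level Confidence level for the interval.
#' @param ci_method `"normal"` (asymptotic, default) or `"percentile"`.
#' @param bounds Optional length-2 metric range to clamp the interval to
#'   (e.g. `c(0, 1)` for proportions and AUC).
#' @param metric_name Label carried in the result.
#' @return List of class `bootstrap_result`: `metric_name`,
#'   `point_estimate`, `se`, `ci_low`, `ci_high`, `n_reps`, `n_dropped`,
#'   `seed`, `replicates`.
#' @export
bootstrap_metric <- function(cohort, metric, n_reps = 2000, seed = 1,
                             ci_level = 0.95,
                             ci_method = c("normal", "percentile"),
                             bounds = NULL, metric_name = "metric") {
  ci_method <- match.arg(ci_method)
  recs <- split_records(cohort)
  if (!length(recs)) stop("empty cohort", call. = FALSE)
  point <- metric(cohort)
  stat <- function(drawn) {
    # disambiguate duplicated patients so per-patient grouping keeps copies
    for (k in seq_along(drawn)) {
      drawn[[k]]$patient_id <- sprintf("%s.%d", drawn[[k]]$patient_id[1L], k)
    }
    metric(bind_records(drawn))
  }
  bs <- bootstrap_patient_stat(recs, stat, n_reps = n_reps, seed = seed)
  ci <- if (ci_method == "normal") {
    asymptotic_ci(point, bs$se, level = ci_level, bounds = bounds)
  } else {
    a <- (1 - ci_level) / 2
    q <- stats::quantile(bs$replicates, c(a, 1 - a), na.rm = TRUE,
                         names = FALSE, type = 7)
    if (!is.null(bounds)) q <- pmin(pmax(q, bounds[1L]), bounds[2L])
    list(ci_low = q[1L], ci_high = q[2L])
  }
  structure(list(metric_name = metric_name, point_estimate = point,
                 se = bs$se, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n_reps = n_reps, n_dropped = bs$n_dropped, seed = seed,
                 replicates = bs$replicates),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s = %.4g (bootstrap se %.4g, 95%% CI %.4g-%.4g, %d reps%s)\n",
              x$metric_name, x$point_estimate, x$se, x$ci_low, x$ci_high,
              x$n_reps,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Normal-approximation confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile at
#' `(1 + level)/2`, optionally clamped to the metric's range.
#'
#' @param estimate Point estimate.
#' @param se Standard error (>= 0).
#' @param level Confidence level in (0, 1).
#' @param bounds Optional length-2 range to clamp to.
#' @return List with `ci_low`, `ci_high`.
#' @export
asymptotic_ci <- function(estimate, se, level = 0.95, bounds = NULL) {
  if (level <= 0 || level >= 1) {
    stop("confidence level must lie in (0, 1)", call. = FALSE)
  }
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  lo <- estimate - z * se
  hi <- estimate + z * se
  if (!is.null(bounds)) {
    lo <- min(max(lo, bounds[1L]), bounds[2L])
    hi <- min(max(hi, bounds[1L]), bounds[2L])
  }
  list(ci_low = lo, ci_high = hi)
}
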