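#' @title Horizon-aligned ROC analysis
#' @name horizon_roc
#' @description
#' Positives are hypotensive events scored by the index value read at a
#' fixed look-back time (the horizon: 5, 10 or 15 min) before event onset;
#' negatives are the centre points of normotensive non-event sections. The
#' classification rule is score >= threshold for a predicted positive,
#' verbatim from the true-positive definition, and strictly below for a
#' predicted negative. The cutpoint is the threshold minimizing
#' |sensitivity - specificity|.
NULL

.nearest_sample <- function(t_s, target, tol) {
  if (!length(t_s)) return(NA_integer_)
  i <- which.min(abs(t_s - target))
  if (abs(t_s[i] - target) > tol) NA_integer_ else i
}

.inside_any_event <- function(t, events) {
  if (is.null(events) || nrow(events) == 0L) return(FALSE)
  any(t >= events$start_t & t <= events$end_t)
}

#' Score at a fixed look-back before an event
#'
#' Reads the predictor at the single sample nearest to
#' `event start - horizon`, within the look-back tolerance (10 s by
#' default). Returns `NA` when no such sample exists (look-back precedes
#' monitoring or falls in a masked hole), when the score itself is missing,
#' or when the look-back sample lies inside another hypotensive event (such
#' a point would not represent a pre-hypotensive state).
#'
#' @param record Masked single-patient data frame.
#' @param event One-row event (from [detect_hypotensive_events()]).
#' @param horizon Look-back, minutes.
#' @param source `"index"` (the record's `score` column) or `"delta_map"`
#'   (see [delta_map_score()]).
#' @param events Full event table for the record, used for the
#'   inside-another-event exclusion.
#' @param cfg A [cohort_config].
#' @return Score (numeric) or `NA`.
#' @export
lookback_score <- function(record, event, horizon,
                           source = c("index", "delta_map"),
                           events = NULL, cfg = cohort_config()) {
  source <- match.arg(source)
  target <- event$start_t - horizon * 60
  i <- .nearest_sample(record$t_s, target, cfg$lookback_tolerance)
  if (is.na(i)) return(NA_real_)
  t_i <- record$t_s[i]
  other <- events
  if (!is.null(other) && nrow(other)) {
    other <- other[other$start_t != event$start_t, , drop = FALSE]
  }
  if (.inside_any_event(t_i, other)) return(NA_real_)
  if (source == "index") {
    record$score[i]
  } else {
    delta_map_score(record, t_i, cfg$delta_map_window, cfg)
  }
}

#' MAP fall over a preceding window
#'
#' `MAP(t - window) - MAP(t)`: positive when pressure has fallen, so a
#' larger score signals higher hypotension risk and ROC thresholds carry
#' the same orientation as the 0-100 index.
#'
#' @param record Masked single-patient data frame.
#' @param t Time of the reading, seconds.
#' @param window Look-back window, minutes.
#' @param cfg A [cohort_config] (supplies the sample-matching tolerance).
#' @return Score in mmHg, or `NA` when either endpoint has no sample within
#'   tolerance.
#' @export
delta_map_score <- function(record, t, window = 15, cfg = cohort_config()) {
  i_now <- .nearest_sample(record$t_s, t, cfg$lookback_tolerance)
  i_then <- .nearest_sample(record$t_s, t - window * 60, cfg$lookback_tolerance)
  if (is.na(i_now) || is.na(i_then)) return(NA_real_)
  record$map[i_then] - record$map[i_now]
}

#' Build the labeled point set for one horizon and score source
#'
#' One positive per event with a defined look-back score at the horizon;
#' one negative per non-event point with a defined score at its centre.
#'
#' @param cohort Masked [hemo_cohort].
#' @param events Cohort-level event table.
#' @param nonevents Cohort-level non-event table.
#' @param horizon Look-back, minutes.
#' @param source `"index"` or `"delta_map"`.
#' @param cfg A [cohort_config].
#' @return Data frame with columns `patient_id`, `t` (seconds; the scored
#'   sample), `label` (1 positive / 0 negative), `score`, `horizon`,
#'   `source`. Errors when either class ends up empty, naming it.
#' @export
build_labeled_set <- function(cohort, events, nonevents, horizon,
                              source = c("index", "delta_map"),
                              cfg = cohort_config()) {
  source <- match.arg(source)
  recs <- split_records(cohort)
  rows <- list()
  for (pid in names(recs)) {
    r <- recs[[pid]]
    ev <- events[events$patient_id == pid, , drop = FALSE]
    ne <- nonevents[nonevents$patient_id == pid, , drop = FALSE]
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        s <- lookback_score(r, ev[k, ], horizon, source, ev, cfg)
        if (!is.na(s)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, t = ev$start_t[k] - horizon * 60, label = 1L,
            score = s, horizon = horizon, source = source,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (nrow(ne)) {
      for (k in seq_len(nrow(ne))) {
        s <- if (source == "index") {
          i <- .nearest_sample(r$t_s, ne$center_t[k], cfg$lookback_tolerance)
          if (is.na(i)) NA_real_ else r$score[i]
        } else {
          delta_map_score(r, ne$center_t[k], cfg$delta_map_window, cfg)
        }
        if (!is.na(s)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, t = ne$center_t[k], label = 0L,
            score = s, horizon = horizon, source = source,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), t = numeric(), label = integer(),
               score = numeric(), horizon = numeric(), source = character(),
               stringsAsFactors = FALSE)
  if (!any(out$label == 1L)) {
    stop("no positive points (no event has a usable look-back score at ",
         horizon, " min)", call. = FALSE)
  }
  if (!any(out$label == 0L)) {
    stop("no negative points (no non-event centre has a usable score)",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds are the unique observed scores plus a sentinel above the
#' maximum; at each, sensitivity = P(score >= threshold | positive) and
#' specificity = P(score < threshold | negative). The AUC integrates the
#' empirical curve over (1 - specificity, sensitivity) by the trapezoidal
#' rule, which equals the tie-adjusted concordance probability (ties count
#' one half).
#'
#' @param points Labeled set from [build_labeled_set()], or any data frame
#'   with numeric `score` and 0/1 `label`.
#' @return List with `thresholds`, `sens`, `spec` (parallel vectors),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(points) {
  pos <- points$score[points$label == 1L]
  neg <- points$score[points$label == 0L]
  if (!length(pos) || !length(neg)) {
    stop("roc_curve needs at least one positive and one negative point",
         call. = FALSE)
  }
  if (anyNA(pos) || anyNA(neg)) stop("scores must not be NA", call. = FALSE)
  thr <- c(sort(unique(c(pos, neg))), Inf)
  sens <- vapply(thr, function(x) mean(pos >= x), numeric(1))
  spec <- vapply(thr, function(x) mean(neg < x), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  x <- c(0, fpr[ord], 1)
  y <- c(0, sens[ord], 1)
  auc <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  list(thresholds = thr, sens = sens, spec = spec, auc = auc,
       n_pos = length(pos), n_neg = length(neg))
}

#' Select the sensitivity-specificity balance cutpoint
#'
#' The threshold minimizing |sensitivity - specificity|; ties broken by the
#' larger sensitivity + specificity, then by the smaller threshold.
#'
#' @param roc Output of [roc_curve()].
#' @return List with `cutpoint`, `sens`, `spec` at it.
#' @export
select_cutpoint <- function(roc) {
  d <- abs(roc$sens - roc$spec)
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    s <- roc$sens[cand] + roc$spec[cand]
    cand <- cand[s == max(s)]
  }
  i <- cand[which.min(roc$thresholds[cand])]
  list(cutpoint = roc$thresholds[i], sens = roc$sens[i], spec = roc$spec[i])
}

#' Confusion-matrix metrics at a threshold
#'
#' TP = positives with score >= threshold, TN = negatives with score <
#' threshold. PPV and NPV are `NA` when their denominator is zero.
#'
#' @param points Labeled set (numeric `score`, 0/1 `label`).
#' @param threshold Classification threshold.
#' @return List: `tp`, `fp`, `tn`, `fn`, `sens`, `spec`, `ppv`, `npv`,
#'   `n_pos`, `n_neg`.
#' @export
confusion_metrics <- function(points, threshold) {
  pos <- points$score[points$label == 1L]
  neg <- points$score[points$label == 0L]
  if (!length(pos) || !length(neg)) {
    stop("confusion_metrics needs both classes", call. = FALSE)
  }
  tp <- sum(pos >= threshold); fn <- length(pos) - tp
  tn <- sum(neg < threshold); fp <- length(neg) - tn
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sens = tp / length(pos), spec = tn / length(neg),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n_pos = length(pos), n_neg = length(neg)
  )
}

#' Predictive values from sensitivity, specificity and class sizes
#'
#' Bayes reconstruction of PPV and NPV from the operating point and the
#' observed numbers of positive and negative data points:
#' `ppv = sens*P / (sens*P + (1-spec)*N)` and
#' `npv = spec*N / (spec*N + (1-sens)*P)`.
#'
#' @param sens,spec Proportions in \[0,1\].
#' @param n_pos,n_neg Positive and negative point counts (> 0).
#' @return List with `ppv` and `npv` (`NA` on a zero denominator).
#' @export
ppv_npv_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            n_pos > 0, n_neg > 0)
  ppv_den <- sens * n_pos + (1 - spec) * n_neg
  npv_den <- spec * n_neg + (1 - sens) * n_pos
  list(
    ppv = if (ppv_den > 0) sens * n_pos / ppv_den else NA_real_,
    npv = if (npv_den > 0) spec * n_neg / npv_den else NA_real_
  )
}
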