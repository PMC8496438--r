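#' @title Pipeline orchestration and report tables
#' @name cli_reporting
#' @description
#' `run_evaluation()` drives the full pipeline (cohort in or synthesized,
#' quality masking, event and non-event extraction, burden metrics,
#' per-horizon ROC for each score source, patient-level bootstrap CIs) and
#' writes the report bundle: a per-patient burden table with median
#' \[IQR\] summaries, a ROC table with one row per (source, horizon), and a
#' JSON manifest with the configuration snapshot, seeds, stage counts and
#' output digests. Reruns with the same configuration and seed are
#' byte-identical.
NULL

#' Median and interquartile range
#'
#' Linear-interpolation order statistics (`stats::quantile` type 7), the
#' convention used for every "median (25th-75th percentile)" summary in the
#' report tables.
#'
#' @param x Numeric vector.
#' @return Named vector `median`, `q25`, `q75`.
#' @export
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  c(median = q[1L], q25 = q[2L], q75 = q[3L])
}

#' Full run configuration
#'
#' @param synth A [synth_config] used when no input CSV is given.
#' @param model An [index_model] for the synthesized scores.
#' @param cohort_csv Optional path to a cohort CSV (see [read_records()]);
#'   when supplied, no synthesis happens.
#' @param cfg A [cohort_config].
#' @param sources Score sources to evaluate (`"index"`, `"delta_map"`).
#' @param n_reps Bootstrap replicates per metric.
#' @param seed Master seed for synthesis and bootstrap.
#' @param ci_level,ci_method Confidence-interval level and method (see
#'   [bootstrap_metric()]).
#' @param out_dir Output directory for the report bundle.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), model = index_model(),
                       cohort_csv = NULL, cfg = cohort_config(),
                       sources = c("index", "delta_map"),
                       n_reps = 2000, seed = 1, ci_level = 0.95,
                       ci_method = "normal", out_dir = "results/run") {
  stopifnot(inherits(synth, "synth_config"), inherits(model, "index_model"),
            inherits(cfg, "cohort_config"))
  sources <- match.arg(sources, c("index", "delta_map"), several.ok = TRUE)
  structure(list(synth = synth, model = model, cohort_csv = cohort_csv,
                 cfg = cfg, sources = sources, n_reps = n_reps, seed = seed,
                 ci_level = ci_level, ci_method = ci_method,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys `synth`, `model`, `cohort`, `evaluation` map onto the
#' arguments of [synth_config()], [index_model()], [cohort_config()] and
#' [run_config()]; unknown keys raise a schema error naming the key.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fn, args, where) {
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop("unknown key '", bad[1L], "' in '", where, "' section",
           call. = FALSE)
    }
    do.call(fn, args)
  }
  ev <- raw$evaluation
  if (!is.null(ev$horizons)) {
    raw$cohort$horizons <- ev$horizons
    ev$horizons <- NULL
  }
  args <- c(list(synth = build(synth_config, raw$synth, "synth"),
                 model = build(index_model, raw$model, "model"),
                 cfg = build(cohort_config, raw$cohort, "cohort")),
            ev)
  bad <- setdiff(names(args), names(formals(run_config)))
  if (length(bad)) {
    stop("unknown key '", bad[1L], "' in 'evaluation' section", call. = FALSE)
  }
  do.call(run_config, args)
}

# bootstrap several metrics from one replicate stream; stat_fn maps pooled
# points to a named numeric vector (NA entries are undefined)
.bootstrap_multi <- function(units, stat_fn, n_reps, seed) {
  proto <- stat_fn(do.call(rbind, units))
  reps <- matrix(NA_real_, n_reps, length(proto),
                 dimnames = list(NULL, names(proto)))
  n <- length(units)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, r))
    idx <- sample.int(n, n, replace = TRUE)
    pooled <- do.call(rbind, units[idx])
    v <- tryCatch(stat_fn(pooled), error = function(e) proto * NA_real_)
    reps[r, ] <- v
  }
  reps
}

#' Evaluate one (source, horizon) cell with bootstrap CIs
#'
#' Builds the labeled set, computes the ROC curve and balance cutpoint on
#' the full cohort, then bootstraps AUC and the fixed-cutpoint sensitivity,
#' specificity, PPV and NPV at the patient level. Labeled points are
#' deterministic per patient, so replicates pool the per-patient point sets
#' of the resampled patients (duplicates contribute duplicate points) —
#' identical to recomputing events and non-events per replicate.
#'
#' @param cohort Masked [hemo_cohort].
#' @param events,nonevents Cohort-level tables.
#' @param horizon Minutes.
#' @param source `"index"` or `"delta_map"`.
#' @param cfg A [cohort_config].
#' @param n_reps,seed,ci_level Bootstrap settings.
#' @param reselect_cutpoint Re-select the cutpoint inside each replicate
#'   instead of fixing it from the full sample (sensitivity analysis;
#'   default `FALSE`).
#' @return One-row data frame mirroring a ROC-table row: counts, AUC,
#'   cutpoint, sens/spec/ppv/npv, each with `_lo`/`_hi` CI columns.
#' @export
evaluate_horizon <- function(cohort, events, nonevents, horizon,
                             source = c("index", "delta_map"),
                             cfg = cohort_config(), n_reps = 2000,
                             seed = 1, ci_level = 0.95,
                             reselect_cutpoint = FALSE) {
  source <- match.arg(source)
  points <- build_labeled_set(cohort, events, nonevents, horizon, source, cfg)
  roc <- roc_curve(points)
  cut <- select_cutpoint(roc)
  cm <- confusion_metrics(points, cut$cutpoint)
  pids <- unique(cohort$patient_id)
  units <- lapply(pids, function(p) points[points$patient_id == p, ,
                                           drop = FALSE])
  fixed_cut <- cut$cutpoint
  stat_fn <- function(pooled) {
    out <- c(auc = NA_real_, sens = NA_real_, spec = NA_real_,
             ppv = NA_real_, npv = NA_real_)
    if (!any(pooled$label == 1L) || !any(pooled$label == 0L)) return(out)
    r <- roc_curve(pooled)
    thr <- if (reselect_cutpoint) select_cutpoint(r)$cutpoint else fixed_cut
    m <- confusion_metrics(pooled, thr)
    c(auc = r$auc, sens = m$sens, spec = m$spec, ppv = m$ppv, npv = m$npv)
  }
  reps <- .bootstrap_multi(units, stat_fn, n_reps, seed)
  point <- c(auc = roc$auc, sens = cm$sens, spec = cm$spec,
             ppv = cm$ppv, npv = cm$npv)
  row <- data.frame(source = source, horizon = horizon,
                    n_pos = roc$n_pos, n_neg = roc$n_neg,
                    cutpoint = cut$cutpoint, stringsAsFactors = FALSE)
  for (m in names(point)) {
    se <- stats::sd(reps[, m], na.rm = TRUE)
    ci <- asymptotic_ci(point[[m]], if (is.finite(se)) se else 0,
                        level = ci_level, bounds = c(0, 1))
    row[[m]] <- point[[m]]
    row[[paste0(m, "_lo")]] <- ci$ci_low
    row[[paste0(m, "_hi")]] <- ci$ci_high
    row[[paste0(m, "_se")]] <- se
  }
  row$n_dropped_reps <- sum(is.na(reps[, "auc"]))
  row
}

#' Run the full evaluation and write the report bundle
#'
#' @param config A [run_config].
#' @param quiet Suppress stage-boundary messages.
#' @return Invisibly, a list with `cohort`, `events`, `nonevents`,
#'   `burden`, `burden_stats`, `roc_table`, `manifest`.
#' @export
run_evaluation <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  synthesized <- is.null(config$cohort_csv)
  cohort <- if (synthesized) {
    sc <- config$synth
    sc$seed <- config$seed
    generate_cohort(sc, config$model)
  } else {
    read_records(config$cohort_csv)
  }
  say("cohort: %d patients, %d samples", length(unique(cohort$patient_id)),
      nrow(cohort))
  masked <- mask_poor_quality(cohort)
  cfg <- config$cfg
  events <- detect_events_cohort(masked, cfg)
  nonevents <- extract_non_events_cohort(masked, events, cfg)
  burden <- burden_cohort(masked, events, cfg)
  say("events: %d; non-event points: %d", nrow(events), nrow(nonevents))

  stats_rows <- rbind(
    data.frame(stat = "events_per_patient", t(median_iqr(burden$n_events))),
    data.frame(stat = "cumulative_hypotension_min",
               t(median_iqr(burden$cumulative_hypotension))),
    data.frame(stat = "total_aut_mmhg_min", t(median_iqr(burden$total_aut))),
    data.frame(stat = "twa_mmhg", t(median_iqr(burden$twa))),
    data.frame(stat = "monitoring_min", t(median_iqr(burden$monitoring_min)))
  )
  alarm_rate <- mean(masked$score >= cfg$alarm_threshold, na.rm = TRUE)

  roc_rows <- list()
  point_counts <- list()
  for (source in config$sources) {
    for (hz in cfg$horizons) {
      row <- tryCatch(
        evaluate_horizon(masked, events, nonevents, hz, source, cfg,
                         n_reps = config$n_reps, seed = config$seed,
                         ci_level = config$ci_level),
        error = function(e) {
          warning("skipping ", source, " at ", hz, " min: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(row)) {
        row$alarm_rate <- if (source == "index") alarm_rate else NA_real_
        roc_rows[[paste(source, hz)]] <- row
        point_counts[[paste0(source, "_", hz, "min")]] <-
          list(n_pos = row$n_pos, n_neg = row$n_neg)
        say("%s @ %g min: AUC %.3f (n_pos %d, n_neg %d)", source, hz,
            row$auc, row$n_pos, row$n_neg)
      }
    }
  }
  roc_table <- if (length(roc_rows)) {
    do.call(rbind, c(roc_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(source = character(), horizon = numeric())
  }

  paths <- list(
    burden = file.path(config$out_dir, "burden.csv"),
    burden_stats = file.path(config$out_dir, "burden_summary.csv"),
    roc = file.path(config$out_dir, "roc.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  if (synthesized) {
    paths$cohort <- file.path(config$out_dir, "cohort.csv")
    write_records(cohort, paths$cohort)
  }
  utils::write.csv(burden, paths$burden, row.names = FALSE)
  utils::write.csv(stats_rows, paths$burden_stats, row.names = FALSE)
  utils::write.csv(roc_table, paths$roc, row.names = FALSE)

  out_files <- unlist(paths[setdiff(names(paths), "manifest")])
  manifest <- list(
    package = "ioheval",
    version = as.character(utils::packageVersion("ioheval")),
    seed = config$seed,
    n_reps = config$n_reps,
    config = list(
      cohort = unclass(config$cfg),
      synth = if (synthesized) unclass(config$synth) else NULL,
      model = if (synthesized) unclass(config$model) else NULL,
      cohort_csv = config$cohort_csv,
      sources = config$sources,
      ci_level = config$ci_level
    ),
    counts = list(
      patients = length(unique(cohort$patient_id)),
      samples = nrow(cohort),
      usable_samples = nrow(masked),
      events = nrow(events),
      non_events = nrow(nonevents),
      labeled_points = point_counts
    ),
    alarm_rate = alarm_rate,
    outputs = as.list(stats::setNames(
      vapply(out_files, function(f) unname(tools::md5sum(f)), character(1)),
      basename(out_files)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, events = events, nonevents = nonevents,
                 burden = burden, burden_stats = stats_rows,
                 roc_table = roc_table, manifest = manifest))
}
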