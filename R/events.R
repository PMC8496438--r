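#' @title Hypotensive events, non-event sections, and burden metrics
#' @name hypotension_events
#' @description
#' A hypotensive event is a maximal run of consecutive 20-s samples with
#' MAP strictly below the threshold (65 mmHg by default), sustained for at
#' least the minimum event duration (60 s, i.e. three samples). Runs are
#' broken by samples at or above the threshold, and by grid gaps left when
#' poor-quality samples are masked out. A non-event is the centre sample of
#' a 30-min fully normotensive section lying at least 20 min from every
#' event boundary. Burden is quantified by the area under the threshold
#' (AUT, mmHg-min) and its time-weighted average (TWA = AUT / monitoring
#' duration, mmHg).
NULL

# run grouping: a new run starts at a change of `below` or at a grid gap
.run_groups <- function(t, below, cfg) {
  n <- length(t)
  if (n == 0L) return(integer())
  gap <- c(FALSE, diff(t) > cfg$sample_interval + cfg$grid_tolerance)
  new_run <- c(TRUE, below[-1L] != below[-n]) | gap
  cumsum(new_run)
}

.empty_events <- function() {
  data.frame(patient_id = character(), start_t = numeric(), end_t = numeric(),
             n_samples = integer(), duration = numeric(), aut = numeric(),
             min_map = numeric(), stringsAsFactors = FALSE)
}

#' Detect hypotensive events in a masked record
#'
#' @param record A single-patient data frame, already passed through
#'   [mask_poor_quality()] (refuses unmasked input so dropouts cannot be
#'   silently bridged).
#' @param cfg A [cohort_config].
#' @return Data frame with one row per event: `patient_id`, `start_t`,
#'   `end_t` (seconds, first and last sub-threshold sample), `n_samples`,
#'   `duration` (minutes, `n_samples` times the sample interval), `aut`
#'   (mmHg-min, rectangular sum of threshold minus MAP over the event), and
#'   `min_map` (mmHg).
#' @export
detect_hypotensive_events <- function(record, cfg = cohort_config()) {
  if (nrow(record) && !all(record$quality_ok)) {
    stop("record contains poor-quality samples; apply mask_poor_quality() ",
         "before event detection", call. = FALSE)
  }
  if (nrow(record) == 0L) return(.empty_events())
  thr <- cfg$map_threshold
  below <- record$map < thr
  grp <- .run_groups(record$t_s, below, cfg)
  min_n <- ceiling(cfg$min_event_duration / cfg$sample_interval)
  keep <- which(vapply(split(seq_len(nrow(record)), grp), function(ix) {
    below[ix[1L]] && length(ix) >= min_n
  }, logical(1)))
  runs <- split(seq_len(nrow(record)), grp)[keep]
  if (!length(runs)) return(.empty_events())
  per_min <- cfg$sample_interval / 60
  out <- do.call(rbind, lapply(runs, function(ix) {
    data.frame(
      patient_id = record$patient_id[ix[1L]],
      start_t = record$t_s[ix[1L]],
      end_t = record$t_s[ix[length(ix)]],
      n_samples = length(ix),
      duration = length(ix) * per_min,
      aut = sum(thr - record$map[ix]) * per_min,
      min_map = min(record$map[ix]),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$start_t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hypotensive events for every patient in a cohort
#'
#' @param cohort A masked [hemo_cohort].
#' @inheritParams detect_hypotensive_events
#' @return Row-bound per-patient event tables (see
#'   [detect_hypotensive_events()]).
#' @export
detect_events_cohort <- function(cohort, cfg = cohort_config()) {
  recs <- split_records(cohort)
  if (!length(recs)) return(.empty_events())
  out <- do.call(rbind, lapply(recs, detect_hypotensive_events, cfg = cfg))
  rownames(out) <- NULL
  out
}

#' Extract non-event points from a masked record
#'
#' Greedy left-to-right tiling of non-overlapping sections of
#' `cfg$section_length` minutes in which every sample has MAP strictly above
#' the threshold with no grid gaps, and whose endpoints lie at least
#' `cfg$section_gap` minutes from every event's start and end. Each section
#' contributes one negative data point at its central sample.
#'
#' @param record A masked single-patient data frame.
#' @param events Event table from [detect_hypotensive_events()] on the same
#'   record.
#' @param cfg A [cohort_config].
#' @return Data frame with columns `patient_id`, `center_t`,
#'   `section_start_t`, `section_end_t` (seconds); zero rows when no section
#'   fits.
#' @export
extract_non_event_points <- function(record, events, cfg = cohort_config()) {
  empty <- data.frame(patient_id = character(), center_t = numeric(),
                      section_start_t = numeric(), section_end_t = numeric(),
                      stringsAsFactors = FALSE)
  n <- nrow(record)
  m <- as.integer(round(cfg$section_length * 60 / cfg$sample_interval))
  if (n < m) return(empty)
  t <- record$t_s
  above <- record$map > cfg$map_threshold
  contiguous <- c(diff(t) <= cfg$sample_interval + cfg$grid_tolerance, FALSE)
  gap_s <- cfg$section_gap * 60
  span_s <- cfg$section_length * 60
  ev_start <- events$start_t
  ev_end <- events$end_t
  # window starting at sample i spans [t[i], t[i] + span_s) and holds
  # samples i..i+m-1; valid iff all above-threshold, internally contiguous,
  # and >= gap_s from every event boundary
  ok_run <- function(i) {
    ix <- i:(i + m - 1L)
    if (!all(above[ix])) return(FALSE)
    if (!all(contiguous[ix[-length(ix)]])) return(FALSE)
    ws <- t[i]; we <- t[i] + span_s
    if (length(ev_start)) {
      clear <- ev_start >= we + gap_s | ev_end <= ws - gap_s
      if (!all(clear)) return(FALSE)
    }
    TRUE
  }
  picks <- integer()
  i <- 1L
  while (i + m - 1L <= n) {
    if (ok_run(i)) {
      picks <- c(picks, i)
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  if (!length(picks)) return(empty)
  center_ix <- picks + m %/% 2L
  data.frame(
    patient_id = record$patient_id[picks],
    center_t = t[center_ix],
    section_start_t = t[picks],
    section_end_t = t[picks] + span_s,
    stringsAsFactors = FALSE
  )
}

#' Extract non-event points for every patient in a cohort
#'
#' @param cohort A masked [hemo_cohort].
#' @param events Cohort-level event table from [detect_events_cohort()].
#' @inheritParams extract_non_event_points
#' @return Row-bound per-patient non-event tables.
#' @export
extract_non_events_cohort <- function(cohort, events, cfg = cohort_config()) {
  recs <- split_records(cohort)
  out <- do.call(rbind, lapply(recs, function(r) {
    ev <- events[events$patient_id == r$patient_id[1L], , drop = FALSE]
    extract_non_event_points(r, ev, cfg)
  }))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), center_t = numeric(),
                      section_start_t = numeric(), section_end_t = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Total area under the MAP threshold, mmHg-min
#'
#' Sums the per-event AUT. Sub-minute dips below the threshold do not form
#' events and contribute nothing.
#'
#' @param record A masked single-patient data frame (unused beyond
#'   signature symmetry; AUT is carried by the events).
#' @param events Event table from [detect_hypotensive_events()].
#' @return Total AUT in mmHg-min (0 when there are no events).
#' @export
area_under_threshold <- function(record, events) {
  if (is.null(events) || nrow(events) == 0L) return(0)
  sum(events$aut)
}

#' Time-weighted average MAP deficit below the threshold, mmHg
#'
#' Total AUT divided by the monitoring duration in minutes over usable
#' samples.
#'
#' @inheritParams area_under_threshold
#' @param sample_interval Sample spacing in seconds.
#' @return TWA in mmHg.
#' @export
twa_map <- function(record, events, sample_interval = 20) {
  dur <- monitoring_minutes(record, sample_interval)
  if (dur <= 0) {
    stop("twa_map: zero usable monitoring duration", call. = FALSE)
  }
  area_under_threshold(record, events) / dur
}

#' Count bradycardia episodes in a record
#'
#' Maximal runs of consecutive samples with HR strictly below the threshold.
#' No minimum duration is imposed by default (a single sub-threshold sample
#' counts), configurable via `min_samples`.
#'
#' @param record A masked single-patient data frame.
#' @param cfg A [cohort_config].
#' @param min_samples Minimum run length, samples.
#' @return Number of episodes.
#' @export
detect_bradycardia <- function(record, cfg = cohort_config(),
                               min_samples = 1L) {
  if (nrow(record) == 0L) return(0L)
  low <- record$hr < cfg$hr_threshold
  grp <- .run_groups(record$t_s, low, cfg)
  runs <- split(low, grp)
  sum(vapply(runs, function(v) v[1L] && length(v) >= min_samples, logical(1)))
}

#' Per-patient hypotension burden summary
#'
#' @param record A masked single-patient data frame.
#' @param events Event table from [detect_hypotensive_events()].
#' @param cfg A [cohort_config].
#' @return One-row data frame: `patient_id`, `n_events`,
#'   `cumulative_hypotension` (minutes), `total_aut` (mmHg-min), `twa`
#'   (mmHg; 0 for an empty record), `monitoring_min`, and
#'   `n_bradycardia_episodes`.
#' @export
burden_summary <- function(record, events, cfg = cohort_config()) {
  dur <- monitoring_minutes(record, cfg$sample_interval)
  aut <- area_under_threshold(record, events)
  n_ev <- if (is.null(events)) 0L else nrow(events)
  data.frame(
    patient_id = if (nrow(record)) record$patient_id[1L] else NA_character_,
    n_events = n_ev,
    cumulative_hypotension = if (n_ev) sum(events$duration) else 0,
    total_aut = aut,
    twa = if (dur > 0) aut / dur else 0,
    monitoring_min = dur,
    n_bradycardia_episodes = detect_bradycardia(record, cfg),
    stringsAsFactors = FALSE
  )
}

#' Burden summaries for every patient in a cohort
#'
#' @param cohort A masked [hemo_cohort].
#' @param events Cohort-level event table.
#' @param cfg A [cohort_config].
#' @return One row per patient (see [burden_summary()]).
#' @export
burden_cohort <- function(cohort, events, cfg = cohort_config()) {
  recs <- split_records(cohort)
  out <- do.call(rbind, lapply(recs, function(r) {
    ev <- events[events$patient_id == r$patient_id[1L], , drop = FALSE]
    burden_summary(r, ev, cfg)
  }))
  rownames(out) <- NULL
  out
}
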