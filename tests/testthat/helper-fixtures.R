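# record/cohort builders and independent brute-force oracles used across
# the test files

make_record <- function(map, pid = "P1", t = NULL, hr = 75, score = NA_real_,
                        quality = TRUE) {
  n <- length(map)
  if (is.null(t)) t <- (seq_len(n) - 1) * 20
  data.frame(
    patient_id = rep_len(pid, n), t_s = t, map = map,
    sbp = map + 20, dbp = map - 10,
    hr = rep_len(hr, n), score = rep_len(score, n),
    quality_ok = rep_len(quality, n),
    stringsAsFactors = FALSE
  )
}

# flat normotensive record of `minutes` minutes
flat_record <- function(minutes, map = 75, pid = "P1", ...) {
  make_record(rep(map, minutes * 3), pid = pid, ...)
}

# random record for oracle-equivalence checks: MAP wanders across the
# threshold, occasional grid gaps from masked dropouts
random_record <- function(n, pid = "P1") {
  map <- round(runif(n, 55, 78), 1)
  keep <- runif(n) > 0.05
  make_record(map[keep], pid = pid, t = ((seq_len(n) - 1) * 20)[keep])
}

# independent maximal-run scan: walks the record sample by sample instead
# of grouping runs, checking maximality explicitly
brute_events <- function(record, cfg = cohort_config()) {
  n <- nrow(record)
  t <- record$t_s
  below <- record$map < cfg$map_threshold
  joined <- function(i) t[i + 1] - t[i] <= cfg$sample_interval + cfg$grid_tolerance
  min_n <- ceiling(cfg$min_event_duration / cfg$sample_interval)
  out <- list()
  i <- 1L
  while (i <= n) {
    starts <- below[i] && (i == 1L || !below[i - 1L] || !joined(i - 1L))
    if (starts) {
      j <- i
      while (j < n && below[j + 1L] && joined(j)) j <- j + 1L
      if (j - i + 1L >= min_n) {
        out[[length(out) + 1L]] <- data.frame(
          start_t = t[i], end_t = t[j], n_samples = j - i + 1L,
          min_map = min(record$map[i:j]),
          aut = sum(cfg$map_threshold - record$map[i:j]) *
            cfg$sample_interval / 60)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# pair-counting concordance AUC with ties counting one half
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# memoized default synthetic evaluation shared across test files
.fixture_env <- new.env(parent = emptyenv())

default_eval <- function() {
  if (is.null(.fixture_env$eval)) {
    cfg <- cohort_config()
    cohort <- generate_cohort(synth_config(seed = 1), index_model())
    masked <- mask_poor_quality(cohort)
    events <- detect_events_cohort(masked, cfg)
    nonevents <- extract_non_events_cohort(masked, events, cfg)
    .fixture_env$eval <- list(cfg = cfg, cohort = cohort, masked = masked,
                              events = events, nonevents = nonevents)
  }
  .fixture_env$eval
}

.empty_events_df <- function() {
  detect_hypotensive_events(flat_record(1, 75))
}

labeled_df <- function(pos, neg) {
  data.frame(
    patient_id = "P1",
    t = seq_len(length(pos) + length(neg)) * 20,
    label = rep(c(1L, 0L), c(length(pos), length(neg))),
    score = c(pos, neg),
    horizon = 5, source = "index",
    stringsAsFactors = FALSE
  )
}
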