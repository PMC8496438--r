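test_that("look-back scoring picks the nearest sample within tolerance", {
  cfg <- cohort_config()
  n <- 75
  r <- make_record(rep(75, n), score = (0:(n - 1)) * 20 / 100)  # score = t/100
  r$map[61:66] <- 60                                            # event at 1200 s
  ev <- detect_hypotensive_events(r, cfg)
  expect_equal(ev$start_t, 1200)

  expect_equal(lookback_score(r, ev[1, ], 5, "index", ev, cfg), 9)    # t = 900
  expect_equal(lookback_score(r, ev[1, ], 15, "index", ev, cfg), 3)   # t = 300
  # look-back preceding monitoring start -> absent
  ev_early <- ev
  ev_early$start_t <- 240
  expect_true(is.na(lookback_score(r, ev_early[1, ], 10, "index", ev, cfg)))

  # jittered grid: the sample at 905 s is within the 10-s tolerance
  rj <- r
  rj$t_s[46] <- 905
  expect_equal(lookback_score(rj, ev[1, ], 5, "index", ev, cfg), 9)
  # but a 30-s offset is not
  rk <- r[-46, ]
  expect_true(is.na(lookback_score(rk, ev[1, ], 5, "index", ev, cfg)))
})

test_that("look-backs landing inside another event are excluded", {
  cfg <- cohort_config()
  map <- rep(75, 90)
  map[31:36] <- 60    # event A: 600-700 s
  map[46:51] <- 60    # event B: 900-1000 s; its 5-min look-back is 600 s
  r <- make_record(map, score = 10)
  ev <- detect_hypotensive_events(r, cfg)
  expect_equal(nrow(ev), 2L)
  expect_true(is.na(lookback_score(r, ev[2, ], 5, "index", ev, cfg)))
  # event A's own look-back is clean
  expect_false(is.na(lookback_score(r, ev[1, ], 5, "index", ev, cfg)))
})

test_that("delta-MAP score is the fall over the window, fall-positive", {
  cfg <- cohort_config()
  expect_equal(delta_map_score(flat_record(20, 75), 1000, 15, cfg), 0)

  n <- 61
  dec <- make_record(80 - (seq_len(n) - 1) / 3)   # falling 1 mmHg/min
  expect_equal(delta_map_score(dec, 1000, 15, cfg), 15)

  ris <- make_record(70 + 0.5 * (seq_len(n) - 1) / 3)  # rising 0.5 mmHg/min
  expect_equal(delta_map_score(ris, 1000, 15, cfg), -7.5)

  expect_true(is.na(delta_map_score(dec, 100, 15, cfg)))  # window precedes start
})

test_that("labeled sets contain one point per usable event and non-event", {
  cfg <- cohort_config()
  map <- rep(75, 360)       # 120 min
  map[235:240] <- 60        # event at minute 78
  map[286:291] <- 60        # event at minute 95
  r <- make_record(map, score = 10)
  ev <- detect_hypotensive_events(r, cfg)
  ne <- extract_non_event_points(r, ev, cfg)
  expect_equal(nrow(ev), 2L)
  expect_equal(nrow(ne), 1L)

  pts <- build_labeled_set(r, ev, ne, 5, "index", cfg)
  expect_equal(sum(pts$label == 1L), 2L)
  expect_equal(sum(pts$label == 0L), 1L)

  # missing either class names it
  expect_error(build_labeled_set(flat_record(100, 75, score = 10),
                                 .empty_events_df(),
                                 extract_non_event_points(
                                   flat_record(100, 75, score = 10),
                                   .empty_events_df(), cfg),
                                 5, "index", cfg),
               "no positive")
  expect_error(build_labeled_set(r[1:270, ], ev[1, ],
                                 ne[0, ], 5, "index", cfg),
               "no negative")

  # at every horizon some events lose their look-back point (out-of-record
  # or inside another event), and never the other way round
  e <- default_eval()
  n_pos <- vapply(c(5, 10, 15), function(h) {
    sum(build_labeled_set(e$masked, e$events, e$nonevents, h, "index",
                          e$cfg)$label == 1L)
  }, numeric(1))
  expect_true(all(n_pos <= nrow(e$events)))
  expect_true(any(n_pos < nrow(e$events)))
})

test_that("ROC curve and AUC match the worked examples", {
  sep <- labeled_df(pos = c(0.8, 0.9), neg = c(0.1, 0.2))
  expect_equal(roc_curve(sep)$auc, 1.0)

  flat <- labeled_df(pos = c(5, 5), neg = c(5, 5))
  expect_equal(roc_curve(flat)$auc, 0.5)

  mix <- labeled_df(pos = c(0.9, 0.4), neg = c(0.5, 0.1))
  roc <- roc_curve(mix)
  expect_equal(roc$auc, 3 / 4)
  cut <- select_cutpoint(roc)
  expect_equal(cut$cutpoint, 0.5)
  expect_equal(cut$sens, 0.5)
  expect_equal(cut$spec, 0.5)

  expect_error(roc_curve(labeled_df(pos = 1, neg = numeric(0))),
               "positive and one negative")
})

test_that("cutpoint ties break by sens+spec then by smaller threshold", {
  # perfectly separated: every threshold in the gap gives sens = spec = 1;
  # the smallest qualifying threshold is returned
  sep <- labeled_df(pos = c(0.8, 0.9), neg = c(0.1, 0.2))
  expect_equal(select_cutpoint(roc_curve(sep))$cutpoint, 0.8)

  # two thresholds with equal |sens - spec|, different sums: higher sum wins
  tie <- labeled_df(pos = 2, neg = c(1, 3))
  roc <- roc_curve(tie)
  d <- abs(roc$sens - roc$spec)
  cand <- roc$thresholds[d == min(d)]
  expect_length(cand, 2L)       # thresholds 2 and 3 both at |d| = 0.5
  cut <- select_cutpoint(roc)
  expect_equal(cut$cutpoint, 2)
  expect_equal(cut$sens + cut$spec, 1.5)
})

test_that("confusion metrics follow the TP/TN definitions", {
  pts <- labeled_df(pos = c(rep(1, 55), rep(0, 9)),
                    neg = c(rep(1, 7), rep(0, 42)))
  m <- confusion_metrics(pts, 0.5)
  expect_equal(m$tp, 55); expect_equal(m$fp, 7)
  expect_equal(m$tn, 42); expect_equal(m$fn, 9)
  expect_equal(m$sens, 55 / 64)
  expect_equal(m$spec, 42 / 49)
  expect_equal(m$ppv, 55 / 62)
  expect_equal(m$npv, 42 / 51)

  lo <- confusion_metrics(pts, -1)
  expect_equal(lo$sens, 1); expect_equal(lo$spec, 0)
  hi <- confusion_metrics(pts, 2)
  expect_equal(hi$sens, 0); expect_equal(hi$spec, 1)
  expect_true(is.na(hi$ppv))
})

test_that("predictive values reconstruct from rates and class sizes", {
  expect_equal(ppv_npv_from_rates(1, 1, 10, 10)$ppv, 1)
  expect_equal(ppv_npv_from_rates(1, 1, 10, 10)$npv, 1)
  b <- ppv_npv_from_rates(0.8, 0.9, 50, 100)
  expect_equal(b$ppv, 0.8 * 50 / (0.8 * 50 + 0.1 * 100))
  expect_equal(b$npv, 0.9 * 100 / (0.9 * 100 + 0.2 * 50))
  expect_error(ppv_npv_from_rates(1.2, 0.5, 10, 10))
})

test_that("AUC equals pair-counting concordance and obeys ROC identities", {
  set.seed(202)
  for (i in 1:60) {
    n_pos <- sample(1:60, 1)
    n_neg <- sample(1:60, 1)
    pos <- round(runif(n_pos, 0, 10), sample(0:2, 1))  # ties likely
    neg <- round(runif(n_neg, 0, 10), sample(0:2, 1))
    pts <- labeled_df(pos, neg)
    roc <- roc_curve(pts)
    expect_equal(roc$auc, brute_auc(pos, neg), tolerance = 1e-12)

    # invariance under a strictly increasing transform
    tr <- pts
    tr$score <- exp(pts$score / 5) + pts$score^3
    expect_equal(roc_curve(tr)$auc, roc$auc, tolerance = 1e-12)

    # label swap complements the AUC
    sw <- pts
    sw$label <- 1L - pts$label
    expect_equal(roc_curve(sw)$auc, 1 - roc$auc, tolerance = 1e-12)

    # the cutpoint's attached sens/spec reproduce under confusion_metrics
    cut <- select_cutpoint(roc)
    cm <- confusion_metrics(pts, cut$cutpoint)
    expect_equal(cm$sens, cut$sens)
    expect_equal(cm$spec, cut$spec)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(303)
  for (i in 1:20) {
    pts <- labeled_df(pos = runif(sample(5:50, 1), 0, 100),
                      neg = runif(sample(5:50, 1), 0, 100))
    ref <- pROC::roc(response = pts$label, predictor = pts$score,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    expect_equal(roc_curve(pts)$auc, as.numeric(pROC::auc(ref)),
                 tolerance = 1e-10)
  }
})
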