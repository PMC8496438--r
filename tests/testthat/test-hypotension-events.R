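test_that("event detection matches the hand-worked examples", {
  cfg <- cohort_config()
  expect_equal(nrow(detect_hypotensive_events(flat_record(5, 70), cfg)), 0L)

  ev <- detect_hypotensive_events(make_record(c(70, 63, 62, 61, 70)), cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_samples, 3L)
  expect_equal(ev$duration, 1.0)
  expect_equal(ev$aut, (2 + 3 + 4) / 3)
  expect_equal(ev$min_map, 61)
  expect_equal(ev$start_t, 20)
  expect_equal(ev$end_t, 60)

  # 40 s below threshold is not an event
  short <- detect_hypotensive_events(make_record(c(70, 60, 60, 70)), cfg)
  expect_equal(nrow(short), 0L)

  # threshold itself belongs to neither side and splits runs
  split_run <- detect_hypotensive_events(
    make_record(c(63, 63, 65, 63, 63, 63)), cfg)
  expect_equal(nrow(split_run), 1L)
  expect_equal(split_run$start_t, 60)
})

test_that("event detection refuses unmasked records and honours holes", {
  r <- make_record(rep(60, 8))
  r$quality_ok[4] <- FALSE
  expect_error(detect_hypotensive_events(r), "mask_poor_quality")

  # the masked hole splits one 8-sample run into 3 + 4: both events
  m <- mask_poor_quality(r)
  ev <- detect_hypotensive_events(m)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_samples, c(3L, 4L))

  # a 3 + 2 split keeps only the first fragment
  r2 <- make_record(rep(60, 6))
  r2$quality_ok[4] <- FALSE
  ev2 <- detect_hypotensive_events(mask_poor_quality(r2))
  expect_equal(nrow(ev2), 1L)
})

test_that("event detection equals the brute-force maximal-run scan", {
  set.seed(101)
  for (i in 1:150) {
    r <- random_record(sample(20:200, 1))
    ev <- detect_hypotensive_events(r)
    br <- brute_events(r)
    if (is.null(br)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(ev$start_t, br$start_t)
      expect_equal(ev$end_t, br$end_t)
      expect_equal(ev$n_samples, br$n_samples)
      expect_equal(ev$aut, br$aut)
      expect_equal(ev$min_map, br$min_map)
    }
    # events are disjoint and ordered; no sample in two events
    if (nrow(ev) > 1L) expect_true(all(diff(ev$start_t) > 0) &&
                                     all(ev$start_t[-1] > ev$end_t[-nrow(ev)]))
  }
})

test_that("non-event sections tile greedily and respect the event gap", {
  cfg <- cohort_config()

  # 100 fully normotensive minutes -> three 30-min sections at 15/45/75 min
  ne <- extract_non_event_points(flat_record(100, 75), .empty_events_df(), cfg)
  expect_equal(nrow(ne), 3L)
  expect_equal(ne$center_t, c(900, 2700, 4500))
  expect_equal(ne$section_start_t, c(0, 1800, 3600))

  # shorter than one section -> none
  expect_equal(nrow(extract_non_event_points(flat_record(29, 75),
                                             .empty_events_df(), cfg)), 0L)

  # 120-min record with an event spanning minutes 55-60: one section before
  # (ends 25 min before the event starts) and one after starting at minute
  # 80, exactly 20 min past the event end
  map <- rep(75, 360)
  map[166:181] <- 60   # t = 3300..3600 s
  r <- make_record(map)
  ev <- detect_hypotensive_events(r, cfg)
  expect_equal(nrow(ev), 1L)
  ne2 <- extract_non_event_points(r, ev, cfg)
  expect_equal(ne2$section_start_t, c(0, 4800))
  expect_equal(ne2$center_t, c(900, 5700))

  # in a 105-min record the post-event section no longer fits
  ne3 <- extract_non_event_points(r[1:315, ], ev, cfg)
  expect_equal(ne3$section_start_t, 0)

  # a sample at exactly the threshold disqualifies its section
  map4 <- rep(75, 90)
  map4[45] <- 65
  expect_equal(nrow(extract_non_event_points(make_record(map4),
                                             .empty_events_df(), cfg)), 0L)

  # sections never overlap events or each other
  e <- default_eval()
  for (pid in unique(e$nonevents$patient_id)) {
    ne_p <- e$nonevents[e$nonevents$patient_id == pid, ]
    ev_p <- e$events[e$events$patient_id == pid, ]
    if (nrow(ne_p) > 1L) {
      expect_true(all(ne_p$section_start_t[-1] >=
                        ne_p$section_end_t[-nrow(ne_p)]))
    }
    if (nrow(ev_p) && nrow(ne_p)) {
      for (k in seq_len(nrow(ne_p))) {
        expect_true(all(ev_p$start_t >= ne_p$section_end_t[k] |
                          ev_p$end_t <= ne_p$section_start_t[k]))
      }
    }
  }
})

test_that("burden metrics follow their definitions", {
  cfg <- cohort_config()

  r0 <- flat_record(60, 75)
  ev0 <- detect_hypotensive_events(r0, cfg)
  expect_equal(area_under_threshold(r0, ev0), 0)
  expect_equal(twa_map(r0, ev0), 0)

  # one 3-sample event at MAP 60 -> AUT = 5 * 3 / 3 = 5
  r1 <- make_record(c(75, 60, 60, 60, 75))
  ev1 <- detect_hypotensive_events(r1, cfg)
  expect_equal(area_under_threshold(r1, ev1), 5)

  # an isolated sub-threshold sample contributes nothing
  r2 <- make_record(c(75, 64, 75, 75))
  ev2 <- detect_hypotensive_events(r2, cfg)
  expect_equal(area_under_threshold(r2, ev2), 0)

  # TWA = AUT / monitoring minutes; masking shrinks the denominator
  map <- rep(75, 540)            # 180 min
  map[100:126] <- 61             # 27 samples at deficit 4 -> AUT 36
  r3 <- make_record(map)
  ev3 <- detect_hypotensive_events(r3, cfg)
  expect_equal(area_under_threshold(r3, ev3), 36)
  expect_equal(twa_map(r3, ev3), 0.2)
  r3m <- r3
  r3m$quality_ok[400:489] <- FALSE   # mask 30 normotensive minutes
  m3 <- mask_poor_quality(r3m)
  expect_equal(twa_map(m3, detect_hypotensive_events(m3, cfg)), 36 / 150)

  expect_error(twa_map(r3[0, ], ev3), "zero usable")
})

test_that("burden summaries aggregate and conserve AUT", {
  cfg <- cohort_config()
  empty <- burden_summary(flat_record(0), .empty_events_df(), cfg)
  expect_equal(empty$n_events, 0L)
  expect_equal(empty$twa, 0)

  map <- rep(75, 60)
  map[10:12] <- 60   # 3-sample event
  map[30:33] <- 58   # 4-sample event
  r <- make_record(map)
  ev <- detect_hypotensive_events(r, cfg)
  b <- burden_summary(r, ev, cfg)
  expect_equal(b$n_events, 2L)
  expect_equal(b$cumulative_hypotension, 7 / 3)
  expect_equal(b$total_aut, sum(ev$aut))
  expect_equal(b$twa * b$monitoring_min, b$total_aut)
})

test_that("burden is translation invariant and monotone in MAP", {
  cfg <- cohort_config()
  set.seed(77)
  for (i in 1:15) {
    r <- random_record(120)
    ev <- detect_hypotensive_events(r, cfg)

    shifted <- r
    shifted$t_s <- r$t_s + 3600
    ev_s <- detect_hypotensive_events(shifted, cfg)
    expect_equal(ev_s$duration, ev$duration)
    expect_equal(ev_s$aut, ev$aut)
    expect_equal(area_under_threshold(shifted, ev_s),
                 area_under_threshold(r, ev))

    # lowering MAP pointwise never shrinks covered time, AUT or TWA
    lower <- r
    lower$map <- r$map - runif(nrow(r), 0, 5)
    ev_l <- detect_hypotensive_events(lower, cfg)
    expect_gte(sum(ev_l$n_samples), sum(ev$n_samples))
    expect_gte(area_under_threshold(lower, ev_l) + 1e-12,
               area_under_threshold(r, ev))

    # appending normotensive time scales TWA down by the duration ratio
    if (nrow(ev)) {
      pad <- make_record(rep(80, 90), t = max(r$t_s) + 20 * (1:90))
      padded <- rbind(r, pad)
      d1 <- monitoring_minutes(r)
      d2 <- monitoring_minutes(padded)
      expect_equal(twa_map(padded, detect_hypotensive_events(padded, cfg)),
                   twa_map(r, ev) * d1 / d2)
    }
  }
})

test_that("bradycardia episodes are counted as strict sub-threshold runs", {
  cfg <- cohort_config()
  expect_equal(detect_bradycardia(flat_record(5, hr = 70), cfg), 0L)
  r <- make_record(rep(75, 10), hr = c(70, 70, 55, 55, 55, 55, 70, 58, 70, 70))
  expect_equal(detect_bradycardia(r, cfg), 2L)
  expect_equal(detect_bradycardia(r, cfg, min_samples = 2L), 1L)
  expect_equal(detect_bradycardia(flat_record(5, hr = 60), cfg), 0L)
})
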