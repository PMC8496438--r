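---
title: "Evaluating early-warning indices for intraoperative hypotension"
author: "ioheval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating early-warning indices for intraoperative hypotension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioheval)
```

## The problem

Intraoperative hypotension — mean arterial pressure (MAP) below 65 mmHg
during anaesthesia — is associated with myocardial and kidney injury in
proportion to its depth and duration. Continuous non-invasive monitors
sample arterial pressure every 20 seconds and can carry a 0–100
early-warning index intended to alarm minutes before pressure actually
falls. `ioheval` implements the standard clinical-performance evaluation
for such an index on 20-s averaged time series:

1. label **hypotensive events** (MAP < 65 mmHg sustained ≥ 1 min) and
   **non-events** (centres of 30-min normotensive sections far from any
   event);
2. read the index at a fixed **look-back horizon** (5, 10 or 15 min)
   before each event onset, and at each non-event centre;
3. summarize discrimination by **ROC/AUC**, with the operating point at
   the threshold where sensitivity and specificity balance;
4. attach **patient-level bootstrap** confidence intervals, because the
   repeated events and sections within a patient are not independent;
5. compare against the naive predictor **ΔMAP**, the fall in MAP over the
   preceding 15 min;
6. quantify hypotensive **burden** per patient: area under the 65-mmHg
   threshold (AUT, mmHg·min) and its time-weighted average
   (TWA = AUT / monitoring duration, mmHg).

Because clinical monitor exports cannot be redistributed, the package
ships a seeded synthetic cohort generator and a pluggable surrogate index
so that every stage is exercised end-to-end by code alone.

## Event and non-event definitions

All detectors run on quality-masked records: samples flagged poor-quality
are removed outright, their time does not count toward monitoring
duration, and the hole they leave breaks any consecutive-sample run. No
interpolation is performed across dropouts — interval averages cannot be
reconstructed honestly, and bridging a gap could manufacture a sustained
event out of two short dips.

A hypotensive event is a *maximal* run of consecutive samples with
MAP strictly below the threshold, lasting at least `min_event_duration`
(60 s, i.e. three 20-s samples). Conventions worth spelling out:

* Clinical phrasing oscillates between "more than 1 min" and "at least
  1 min". We adopt **≥ 60 s** (three samples), matching the definition
  used for true positives; it is configurable.
* A sample at exactly 65 mmHg belongs to neither events (strict `<`) nor
  non-event sections (strict `>`), and it splits a sub-threshold run in
  two. Runs are never merged across recoveries: a single at-or-above
  threshold sample ends an event.
* Event duration is `n_samples × 20 s`: each interval-averaged sample
  represents 20 s of exposure. For the same reason AUT uses rectangular
  integration, `Σ (65 − MAP_i) × 1/3` mmHg·min, not trapezoids.
* AUT integrates only over samples inside qualifying events, so
  sub-minute dips contribute nothing to burden. TWA divides by monitoring
  minutes over usable samples, so masking time raises TWA for the same
  AUT.

Non-event sections are found by **greedy left-to-right tiling**: scan the
record for the earliest 30-min window in which every sample is strictly
normotensive with no grid gaps and both window endpoints are at least
20 min from every event boundary; emit its central sample as the negative
point; resume scanning after the window. Greedy tiling is deterministic,
allows several non-events per patient (cohort evaluations report more
negatives than patients, so a one-per-patient cap would be wrong), and
never overlaps sections. Event boundaries are the timestamps of the first
and last sub-threshold samples.

## Horizon-aligned labelling

The positive point for an event at horizon *h* is the score at the single
sample nearest to `start − h`, accepted only within ±10 s. A windowed
maximum would inflate sensitivity; the definition names a time point, so
we read a time point. The look-back is discarded when

* it precedes the record or falls in a masked hole, or
* it lies inside *another* hypotensive event — a sample during ongoing
  hypotension does not represent a pre-hypotensive state.

Both mechanisms shrink the positive count relative to the event count,
and they interact with event spacing: when events cluster a few minutes
apart, the short 5-min look-back is excluded more often than the 15-min
one. Per-horizon positive counts are therefore reported alongside every
ROC row rather than assumed monotone in the horizon.

ΔMAP is scored as `MAP(t − 15 min) − MAP(t)`: positive when pressure has
fallen, so larger values mean higher risk and ROC thresholds keep the
same orientation as the index.

## ROC conventions

Predicted positive means **score ≥ threshold** (weak inequality, exactly
as the true-positive definition reads); predicted negative means
score < threshold. Thresholds are the unique observed scores plus a
sentinel above the maximum, so the empirical curve runs from (1,1) to
(0,0). AUC is the trapezoidal integral over (1 − specificity,
sensitivity), which equals the tie-adjusted concordance probability
(ties count ½); the test suite verifies this equality against a
pair-counting oracle and against an independent ROC implementation.

The cutpoint is the threshold minimizing `|sensitivity − specificity|`;
ties break toward the larger `sensitivity + specificity`, then toward the
smaller threshold (so with perfectly separated classes the smallest
qualifying threshold is returned). PPV and NPV are reported as absent
when their denominator is empty, and can also be reconstructed from
(sens, spec, P, N) via `ppv_npv_from_rates()` — useful for checking
published operating points.

## Patient-level bootstrap

Within-patient repeated measures are handled by resampling **whole
patients**: each of `n_reps` (default 2000) replicates draws N patients
with replacement from the N observed, recomputes the metric on the
resampled cohort, and the standard error is the SD of the replicate
metrics (denominator `n_reps − 1`). Confidence intervals are
normal-approximation `estimate ± z·se` ("asymptotic"), clamped to the
metric's range; percentile intervals are available as an option.

Design choices the literature leaves open:

* **Cutpoint handling.** By default the cutpoint is selected once on the
  full sample and replicates evaluate sens/spec/PPV/NPV at that fixed
  threshold; `reselect_cutpoint = TRUE` re-selects per replicate as a
  sensitivity analysis. Re-selection mixes cutpoint variability into
  operating-point variability, which is not what a fixed published
  cutpoint implies.
* **Undefined replicates** (e.g. a resample with no positives) are
  dropped and counted; more than 50% undefined aborts with an error
  rather than reporting a meaningless interval.
* **Reproducibility.** One master seed spawns a deterministic substream
  per replicate (and, in the generator, per patient), so results do not
  depend on evaluation order.
* Per-patient labeled points are a deterministic function of that
  patient's record, so replicates pool precomputed per-patient point
  sets; a duplicated patient contributes its points twice. This is
  algebraically identical to recomputing events and non-events on the
  resampled cohort, and much faster.

## The synthetic cohort

The generator emulates the summary structure such evaluations are run
on — about 31 patients, median monitoring ≈ 194 min (lognormal,
sdlog 0.6), roughly three quarters of patients with at least one event, a
few events per affected patient with median sub-threshold duration
≈ 2.67 min, and TWA of a few tenths of a mmHg:

* **Baseline MAP** is an Ornstein–Uhlenbeck process around 80 mmHg
  (mean reversion 0.2/min, stationary SD 2.2 mmHg), discretized exactly
  on the 20-s grid.
* **Episodes** arrive as a Poisson process (4/h baseline) thinned to
  non-overlapping supports, with a mean-1 gamma **frailty** (shape 0.8)
  multiplying each patient's rate. The frailty reproduces the clinical
  overdispersion — some patients stay event-free while others accumulate
  many clustered events.
* **Episode shape**: a smooth prodromal decline (raised-cosine ramp,
  11 mmHg over 10 min), a raised-cosine dip whose depth below threshold
  is gamma-distributed (mean 8 mmHg) and whose width is solved so the
  designed sub-threshold time is lognormal with median 2.67 min, then a
  3-min recovery ramp. The prodrome is a deliberate design choice: with
  realistic sub-threshold durations, a bare dip crosses 65 mmHg within
  ~2 min of its onset, so a 5-min-ahead look-back would sit on a flat
  series and *no* pressure-derived predictor could discriminate there.
  A gradual compensatory decline before overt hypotension is also the
  physiologic premise behind waveform-based warning indices.
* **Heart rate** is its own OU process around 73 bpm (so bradycardic runs
  below 60 bpm occur occasionally); systolic/diastolic pressures are
  derived from MAP with a noisy pulse pressure; 2% of samples are flagged
  poor-quality at random.

The **surrogate index** fits a least-squares MAP trend over the preceding
3 min (nine samples — the shortest window giving a stable slope on noisy
series), extrapolates it 5 min ahead, and maps the predicted MAP through
a logistic centred at 65 mmHg (slope 0.5 per mmHg), plus Gaussian index
noise (SD 3), clipped to [0,100]. The **null index** is i.i.d. uniform on
[0,100] — exactly exchangeable with the labels (unlike a shuffled
surrogate, whose within-patient autocorrelation would survive the
shuffle), so its AUC must concentrate at 0.5; the suite checks that the
patient-level bootstrap interval around a null AUC covers 0.5 at every
horizon.

What the generator does **not** model: vasopressor/fluid interventions
truncating events, HR–MAP coupling, circadian or surgical-phase trends,
waveform-level artefacts (quality is a Bernoulli flag), and any real
relationship between waveform features and impending hypotension beyond
the MAP trend itself. Passing the synthetic discrimination checks
therefore demonstrates that the *evaluation machinery* is correct — it
says nothing about any proprietary index on real patients, and the
printed AUCs/cutpoints of clinical studies are explicitly not
reproduction targets.

Generator parameters were fixed once against the cohort summaries above
(Monte-Carlo over 20 seeded replicates) and are not tuned per analysis;
under the defaults the surrogate reaches AUC ≥ 0.9 at the 5-min horizon
while ΔMAP stays clearly weaker at every seed examined, mirroring the
qualitative ordering such comparisons report.

## Numerical conventions and degenerate inputs

* Nominal grid 20 s with ±2 s jitter tolerance; larger deviations are
  gaps, reported by `validate_record()` and breaking all run-based
  detectors.
* Median [IQR] summaries use linear-interpolation order statistics
  (`quantile` type 7).
* CSV round trips write numerics with 17 significant digits, so
  `read_records(write_records(x))` is exact; absent scores are empty
  cells, never 0.
* Empty records yield all-zero burden summaries; TWA on a record with no
  usable time is an error, not 0/0.
* All-flagged records mask to an empty record with a warning, not an
  error.
* z for the 95% asymptotic interval is `qnorm(0.975) ≈ 1.959964`.

## Problem sizes

The test suite runs the full default scenario (31 patients, ≈ 190 min
median monitoring) once and shares it across files; oracle-equivalence
checks use 1000 random records of up to 500 samples and 1000 random
labeled sets of up to 200 points; bootstrap checks use 2000 replicates
where an interval is asserted and 100–300 where only determinism or
bookkeeping is under test. The whole suite completes in well under five
minutes on one core.

## A small worked run

```{r example, message = TRUE}
cfg <- cohort_config()
cohort <- generate_cohort(synth_config(n_patients = 8, seed = 1))
masked <- mask_poor_quality(cohort)
events <- detect_events_cohort(masked, cfg)
nonevents <- extract_non_events_cohort(masked, events, cfg)
burden <- burden_cohort(masked, events, cfg)
summary(burden$twa)

pts <- build_labeled_set(masked, events, nonevents, 5, "index", cfg)
roc <- roc_curve(pts)
select_cutpoint(roc)
roc$auc
```

`run_evaluation()` wraps all of the above, adds the bootstrap CIs, and
writes the burden table, the ROC table and a manifest whose digests make
seeded reruns verifiably byte-identical. The `analysis/` scripts in the
repository drive the same steps as a narrated workflow.

## Known limitations

* The negative class is typically small (normotensive 30-min stretches
  ≥ 20 min from events are scarce in event-rich records), so specificity
  CIs are wide; this matches the structure of the clinical evaluations
  the package mirrors.
* Cutpoints are on the surrogate's own scale and are not comparable to
  published cutpoints of proprietary indices.
* The bootstrap treats the patient as the only clustering level; day or
  operator effects are out of scope.
* Bradycardia episodes have no minimum duration (a single sub-60 bpm
  sample counts), configurable via `min_samples`.
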