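# ioheval

Lead-time ROC evaluation of early-warning indices for intraoperative
hypotension, on 20-second averaged arterial-pressure time series.

## The problem

Intraoperative hypotension — mean arterial pressure (MAP) below 65 mmHg —
is common under anaesthesia and harmful in proportion to its depth and
duration. Continuous monitors can carry a 0–100 prediction index meant to
warn minutes ahead. Judging such an index requires a whole evaluation
pipeline, not just an AUC call:

* **Events**: maximal runs of 20-s samples with MAP < 65 mmHg sustained
  ≥ 1 min, each with duration, nadir, and area under the threshold
  (AUT = Σ (65 − MAP_i) · ⅓ mmHg·min).
* **Non-events**: centres of 30-min fully normotensive sections lying
  ≥ 20 min from every event boundary, tiled greedily and without overlap.
* **Horizon labelling**: the positive for an event at horizon *h* ∈
  {5, 10, 15} min is the score at the sample nearest `start − h` (±10 s),
  discarded if it falls off-record or inside another event; each
  non-event centre is a negative.
* **ROC**: predicted positive ⇔ score ≥ threshold; AUC by the trapezoidal
  rule (equal to tie-adjusted concordance); the reported operating point
  is the cutpoint minimizing |sensitivity − specificity|, with
  PPV = sens·P / (sens·P + (1−spec)·N) and
  NPV = spec·N / (spec·N + (1−sens)·P).
* **Inference**: patient-level bootstrap (N patients resampled with
  replacement, 2000 replicates) with normal-approximation 95% CIs, because
  events and sections repeat within patients.
* **Comparator**: ΔMAP, the fall in MAP over the preceding 15 min
  (fall-positive).
* **Burden**: per-patient event counts, cumulative hypotension minutes,
  total AUT, and TWA = AUT / monitoring minutes.

A seeded synthetic intraoperative cohort generator (Ornstein–Uhlenbeck
MAP around 80 mmHg plus smooth prodrome–dip–recovery hypotensive episodes,
gamma frailty across patients) and a pluggable surrogate index (logistic
of a 3-min MAP trend extrapolated 5 min ahead; uniform null index as a
negative control) make the whole pipeline testable without patient data.
See `vignettes/hypotension-evaluation.Rmd` for the full methods account.

## Worked example

The `analysis/` scripts narrate a complete run on the default synthetic
cohort (31 patients, seed 1):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_detect_events.R
Rscript analysis/03_roc_evaluation.R
Rscript analysis/04_full_report.R   # adds 2000-rep bootstrap CIs
```

`02_detect_events.R` prints the cohort burden:

```
142 hypotensive events in 26 of 31 patients (83.9%)
events per patient (median [IQR]):      2.00 [1.00, 6.50]
event duration, min (median [IQR]):     2.33 [1.67, 4.00]
cumulative hypotension, min:            5.33 [1.50, 18.50]
TWA MAP deficit, mmHg (median [IQR]):   0.21 [0.04, 0.59]
non-event points: 18
```

— 26 of the 31 simulated patients had at least one sustained sub-65 mmHg
event; the median affected patient spent 5.3 min hypotensive with a
time-weighted deficit of 0.21 mmHg. `03_roc_evaluation.R` then scores
every event look-back and non-event centre:

```
index     @  5 min: AUC 0.924, cutpoint   4.76, sens 0.88, spec 0.89 (121+/18-)
index     @ 10 min: AUC 0.595, cutpoint   0.80, sens 0.56, spec 0.56 (131+/18-)
delta_map @  5 min: AUC 0.667, cutpoint   1.57, sens 0.65, spec 0.67 (111+/18-)
finding: the trend surrogate dominates delta-MAP at 5 min (0.924 vs 0.667)
```

The surrogate discriminates strongly at its 5-min design horizon
(AUC 0.92: at the balance cutpoint it catches 88% of events five minutes
ahead while flagging 11% of quiet sections), decays toward chance at
horizons beyond its lead, and clearly beats the naive ΔMAP comparator.
Cutpoints are on the surrogate's own score scale. `04_full_report.R`
writes the same table with bootstrap CIs, the burden tables, and a
manifest with file digests under `results/report/`; identical seeds give
byte-identical bundles.

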