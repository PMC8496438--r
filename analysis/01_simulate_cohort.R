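#!/usr/bin/env Rscript
# Simulate the default intraoperative cohort: 31 patients monitored with
# 20-s averaged non-invasive arterial pressure, a trend-following surrogate
# prediction index, and quality dropouts. Writes results/cohort.csv.

library(ioheval)

seed <- 1
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(synth_config(seed = seed), index_model())
write_records(cohort, "results/cohort.csv")

n_pat <- length(unique(cohort$patient_id))
minutes <- vapply(split_records(cohort), monitoring_minutes, numeric(1))
message(sprintf("simulated %d patients, %d samples (%.0f patient-hours)",
                n_pat, nrow(cohort), sum(minutes) / 60))
message(sprintf("monitoring per patient: median %.0f min (IQR %.0f-%.0f)",
                median_iqr(minutes)[1], median_iqr(minutes)[2],
                median_iqr(minutes)[3]))
message(sprintf("poor-quality samples: %.1f%%",
                100 * mean(!cohort$quality_ok)))
message("wrote results/cohort.csv")
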