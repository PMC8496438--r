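#!/usr/bin/env Rscript
# Detect hypotensive events (MAP < 65 mmHg sustained >= 1 min), extract
# 30-min normotensive non-event sections, and summarize the hypotension
# burden per patient. Reads results/cohort.csv from 01_simulate_cohort.R.

library(ioheval)

if (!file.exists("results/cohort.csv")) {
  stop("run analysis/01_simulate_cohort.R first")
}
cfg <- cohort_config()
cohort <- read_records("results/cohort.csv")
masked <- mask_poor_quality(cohort)

events <- detect_events_cohort(masked, cfg)
nonevents <- extract_non_events_cohort(masked, events, cfg)
burden <- burden_cohort(masked, events, cfg)

write.csv(events, "results/events.csv", row.names = FALSE)
write.csv(nonevents, "results/nonevents.csv", row.names = FALSE)
write.csv(burden, "results/burden.csv", row.names = FALSE)

fmt <- function(x) sprintf("%.2f [%.2f, %.2f]", x[1], x[2], x[3])
message(sprintf("%d hypotensive events in %d of %d patients (%.1f%%)",
                nrow(events), sum(burden$n_events >= 1), nrow(burden),
                100 * mean(burden$n_events >= 1)))
message("events per patient (median [IQR]):      ",
        fmt(median_iqr(burden$n_events)))
message("event duration, min (median [IQR]):     ",
        fmt(median_iqr(events$duration)))
message("cumulative hypotension, min:            ",
        fmt(median_iqr(burden$cumulative_hypotension)))
message("TWA MAP deficit, mmHg (median [IQR]):   ",
        fmt(median_iqr(burden$twa)))
message(sprintf("non-event points: %d", nrow(nonevents)))
message("wrote results/{events,nonevents,burden}.csv")
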