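Package: ioheval
Title: Lead-Time ROC Evaluation of Intraoperative Hypotension Early-Warning Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate early-warning indices for intraoperative
    hypotension on 20-second averaged non-invasive arterial-pressure time
    series: detection of hypotensive events (mean arterial pressure below
    65 mmHg sustained for at least one minute), extraction of normotensive
    non-event sections, hypotension-burden metrics (area under the 65 mmHg
    threshold and its time-weighted average), horizon-aligned ROC analysis
    with cutpoint selection at the sensitivity-specificity balance point, a
    delta-MAP comparator, and patient-level bootstrap confidence intervals.
    Includes a seeded synthetic intraoperative cohort generator with a
    pluggable surrogate prediction index so the full pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
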