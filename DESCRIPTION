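Package: pupiltiming
Title: Pupillometry and Sequential-Adjustment Analysis for Time-Estimation Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for interval-timing experiments with
    concurrent pupillometry. Provides trial-level behavioral scoring (timing
    errors, clamped feedback values, trial-to-trial adjustment regression),
    pupil signal cleaning (eye selection by confidence, artifact detection via
    confidence and derivative criteria, interpolation, zero-phase Butterworth
    band-pass filtering, per-block median normalization), event-locked epoch
    extraction with baseline correction and rule-based trial rejection,
    time-resolved one-sample statistics and single-trial regression of pupil
    dilation on performance error, and 2x2 mixed-design group inference
    (mixed ANOVA with partial eta squared, adjusted one-sample t-tests, rank
    tests, Pearson correlations). Includes a forward simulator that generates
    complete synthetic cohorts (behavior, binocular 60 Hz pupil streams with
    blink-like artifacts, metadata) with a known ground-truth ledger, so every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
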