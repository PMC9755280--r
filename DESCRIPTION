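Package: conformalqc
Title: Conformal Prediction Quality Control for Classifier Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mondrian inductive conformal prediction over per-example class
    probability vectors, aimed at quality control of AI-assisted diagnostic
    classifiers such as prostate biopsy grading systems. Provides
    train/calibration splitting (optionally grouped by subject),
    class-conditional calibration, smoothed and non-smoothed conformal
    p-values, prediction regions under global or class-wise confidence
    levels, region tallies (error/empty/single/multiple) and efficiency,
    calibration-curve validity diagnostics, panel-vote coverage, a simulated
    human-in-the-loop AUC experiment, Kolmogorov-Smirnov drift detection
    against a calibration set, resampling-based power and sample-size
    estimation for drift detection, and a synthetic probability-score
    generator with shift and contamination scenarios for end-to-end
    validation of the conformal guarantee.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
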