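Package: muacscreen
Title: Diagnostic Accuracy of Mid-Upper Arm Circumference Screening for
    Adolescent Thinness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate mid-upper arm circumference (MUAC) as a
    surrogate for BMI-for-age z-scores (BAZ) when screening adolescent
    girls for thinness. Implements LMS growth-reference z-scoring with
    the WHO restricted-adjustment convention, ROC curve construction
    with trapezoidal AUC, DeLong confidence intervals and Youden-optimal
    cutoff selection, the full 2x2 diagnostic metric set (sensitivity,
    specificity, likelihood ratios, predictive values) with exact and
    log-method confidence intervals, technical error of measurement and
    test-retest reliability statistics, diagnostic-accuracy sample-size
    calculation, and a calibrated synthetic-cohort generator with known
    population correlation and AUC for validation studies.
License: MIT + file LICENSE
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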