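Package: ovaclock
Title: Ovarian Reserve Scoring, Endocrine Age and Reproductive Milestone
    Prediction from AMH and Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for individualized ovarian reserve assessment from serum
    anti-Mullerian hormone (AMH) and chronological age. Fits polynomial
    logistic regression models for poor ovarian response (POR, fewer than
    five oocytes retrieved), converts predicted POR probability to a 0-100
    ovarian reserve score, constructs a population ovarian-aging curve by
    fitting a two-parameter logistic to per-age predicted-DOR proportions,
    inverts that curve to an "endocrine age", and projects the chronological
    ages at which future reserve milestones (score 50, perimenopause) will
    be reached under the fixed-interval hypothesis. Includes discrimination,
    calibration and net reclassification metrics, seeded synthetic ART
    cohort generators calibrated to published summary statistics, a
    stimulation-day AMH decline model for sensitivity analysis, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
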