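Package: pessaryfit
Title: PLS-VIP Prediction of Pessary-Fitting Success from Dynamic MRI
    Pelvic-Floor Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a partial least squares (PLS1) analysis pipeline for
    small clinical cohorts of women with pelvic organ prolapse, aimed at
    predicting whether a vaginal pessary will fit from anatomical parameters
    measured on dynamic pelvic-floor MRI. Provides the 78-variable
    measurement grid (parameter x manoeuvre x pessary condition), z-score
    preprocessing with near-zero imputation of missing cells, NIPALS PLS1
    regression with per-component explained variance, variable importance in
    projection (VIP) scoring and ranking, top-k variable selection,
    exhaustive leave-one-out and leave-two-out cross-validation with a
    trichotomous fitting/non-fitting/unknown decision rule, baseline
    group-comparison statistics (pooled summaries, t-test, exact
    Mann-Whitney U, exact contingency tests), and a synthetic-cohort
    generator with correlated anatomical variables for validating the
    pipeline when clinical data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
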