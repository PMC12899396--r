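Package: koawear
Title: Diurnal Accelerometer Activity Patterns and Knee Osteoarthritis
    Symptom Worsening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing hip-worn accelerometer activity-count
    data in longitudinal knee-osteoarthritis cohorts. Implements windowed
    non-wear detection with a bounded interruption allowance, valid-day and
    valid-participant wear filters, Freedson count cut-point intensity
    classification (sedentary, light, moderate-to-vigorous), 3-hour diurnal
    activity segmentation restricted to daytime wear, WOMAC minimal
    clinically important difference responder classification, worse-knee
    radiographic derivations with adjacent-visit imputation, and a
    Stable-versus-Worsening two-group comparison battery (Shapiro-Wilk
    gated t / Mann-Whitney tests, chi-square for categorical variables).
    Includes a seeded synthetic cohort generator emulating the structure of
    a 7-day, two-visit accelerometer sub-study so the full pipeline is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
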