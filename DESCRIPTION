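Package: intakeval
Title: Validation Toolkit for Leftover-Based Food Intake Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating methods that estimate hospitalized
    patients' food intake from leftover observations. Implements the
    11-point converted intake scale used in clinical plate-waste studies,
    conversion of weighed pre/post meal measurements to that scale,
    nutrient-intake computation from menu composition tables, and a full
    method-agreement analysis (RMSE, mean-reference R-squared, signed and
    absolute mean error, Spearman rank correlation, paired t tests,
    tie-corrected Friedman tests, Bland-Altman limits of agreement, and
    ordinal 11x11 confusion matrices). A seeded synthetic-cohort generator
    emulates the dish composition, intake distribution and per-method rater
    error structure of a liquid-food validation study, so the whole
    pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
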