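Package: tastecca
Title: Correlation and Canonical Correlation Analysis of Taste, Questionnaire,
    Brain-Activity, and Fruit-Composition Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for sensory-evaluation studies that relate a continuous
    taste rating (visual analog scale) to questionnaire responses, fNIRS
    brain-activity recordings, and per-fruit composition measurements.
    Provides the printed study tables of a 19-participant, four-strawberry
    tasting experiment as fixtures, epoch-locked statistical feature
    extraction for multichannel oxy-/deoxy-hemoglobin traces, PCA with
    cumulative-variance dimension selection, a Pearson correlation screen
    with two-sided t-test p-values, canonical correlation analysis solved
    as a ridge-regularized generalized eigenproblem with cross-loadings and
    Bartlett or permutation significance, and a synthetic-study generator
    with planted cross-block correlations for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
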