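Package: mapdeficit
Title: Relative-Hypotension Exposure Metrics and Trial Analytics for
    Individualized Blood-Pressure Targets in ICU Shock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying relative hypotension (mean-arterial-pressure
    deficit) among vasopressor-treated ICU patients and for analysing pilot
    randomized trials of individualized versus standard blood-pressure targets.
    Implements pre-illness MAP estimation from historical readings, eligibility
    screening, time-weighted positive incremental area-under-the-curve deficit
    metrics, KDIGO-based renal composite endpoints (MAKE-14, new significant
    AKI), permuted-block stratified randomization, exact and rank-based group
    comparisons, random-intercept mixed models for repeated hemodynamic
    measures, two-proportion and two-mean sample-size calculators with
    attrition inflation, and a seeded synthetic-cohort generator that emulates
    the trial's data structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
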