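Package: dbsagree
Title: Method Agreement and Predictive Performance for Dried Blood Spot
    Drug Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Clinical cross-validation toolkit for dried blood spot (DBS)
    assays against venous whole-blood reference measurements, built around
    everolimus therapeutic drug monitoring in oncology. Provides from-scratch
    Passing-Bablok regression with rank-based confidence intervals and
    constant/proportional bias calls, ratio-scale Bland-Altman agreement with
    limits of clinical relevance and a design-stage power/sample-size
    calculation, leave-one-out predictive performance with the Sheiner-Beal
    median error statistics and regulatory acceptance verdicts, log-linear
    trough extrapolation with therapeutic-window classification, a synthetic
    paired-cohort generator for end-to-end testing, and a one-call validation
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
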