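Package: tikdscreen
Title: Diagnostic Yield Analysis for Targeted Tubulointerstitial Kidney
    Disease Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic-epidemiology screens of hereditary
    tubulointerstitial kidney disease in clinical chronic kidney disease
    registries. Implements clinical-category cohort filtering with
    age cutoffs and quality-control gates, ACMG/AMP five-tier categorical
    variant classification alongside the Bayesian posterior probability of
    pathogenicity (odds-of-pathogenicity framework), diagnostic-yield and
    exact-binomial category-enrichment statistics, and a resampling null
    comparing panel yield against a reference exome cohort. Includes
    synthetic registry and reference-cohort generators emulating the GCKD
    tubulointerstitial screen, plus a packaged transcription of its
    published diagnostic-variant list.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
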