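Package: folatecog
Title: Nonlinear Folate and Vitamin B12 Dose-Response Analysis for
    Cognitive Aging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inverted-U (reverse U-shaped) associations
    between folate and vitamin B12 biomarkers and cognitive test performance
    in older-adult cohorts. Provides cohort derivation rules (CKD-EPI
    estimated glomerular filtration rate, low vitamin B12 classification,
    cognitive impairment flags, dietary folate equivalents, eligibility
    filtering with an exclusion audit), restricted cubic spline regression
    with likelihood-ratio tests for non-linearity and effect modification,
    single change-point (two-line piecewise linear) estimation by exhaustive
    profile likelihood, K-means subgrouping of biomarker profiles with
    Calinski-Harabasz selection of the number of clusters and bootstrap
    Jaccard cluster stability, baseline comparison tables, and a synthetic
    cohort generator with known ground truth for validation.
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
    tools,
    utils,
    withr
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
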