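Package: prostascore
Title: Accumulating Diagnostic Risk Scores for Prostate Cancer from
    PI-RADS v2 and PSA Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating integer "accumulating"
    risk scores for prostate cancer diagnosis that combine the PI-RADS v2
    imaging category with ordinal levels of serum PSA, PSA density and the
    free/total PSA ratio.  Provides ordinal stratification of the serum
    markers, a registry of thirteen weighted scoring models plus the
    PI-RADS-only baseline, and an evaluation suite covering operating
    points at score cut-offs, ROC curves and AUC, Youden cut-off
    selection, Gleason-group score summaries with Student-t confidence
    intervals, one-way ANOVA, tie-corrected Kendall tau-b, and logistic
    regression odds ratios.  A Gaussian-copula cohort simulator generates
    labelled synthetic cohorts whose marginal distributions, group
    structure and ordinal correlations emulate a biopsy referral
    population, so the whole pipeline is testable without patient data.
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
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
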