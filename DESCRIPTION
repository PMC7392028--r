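Package: hdrisktree
Title: Survival Regression Trees and Accuracy Indices for Cardiovascular
    Risk Stratification in Hemodialysis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for stratifying cardiovascular risk in hemodialysis
    cohorts from clinical covariates and circulating microRNA levels.
    Implements RT-qPCR delta-Cq normalization with floor censoring of
    undetected assays, case/control biomarker evaluation (rank tests,
    Cox regression under several missing-data strategies including
    chained-equation multiple imputation, ROC AUC, fold-change
    screening), CART-style recursive partitioning of right-censored
    outcomes with Harrington-Fleming weighted log-rank split statistics
    and surrogate splits, bagging for variable selection frequency and
    surrogate-aware importance, and accuracy indices for an ordinal risk
    partition: the integrated cumulative/dynamic time-dependent AUC
    (iAUC) and an incidence-rate variation index (IRV). A synthetic
    cohort generator with a latent eight-leaf risk-tree structure,
    matched or random case/control sampling and MCAR missingness
    supports testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
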