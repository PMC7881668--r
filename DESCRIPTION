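Package: kwlpr
Title: Kernel-Weighted Local Polynomial Regression for QSAR/QSAAR Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric quantitative structure-activity (QSAR) and
    structure-activity-activity (QSAAR) modeling by kernel-weighted local
    polynomial regression. Provides local-constant (Nadaraya-Watson) and
    local-linear estimators with per-descriptor product-kernel weighting
    (Gaussian, Epanechnikov, uniform), automatic bandwidth selection by
    least-squares cross-validation, corrected-AIC cross-validation and the
    direct plug-in method, the full QSAR validation panel (R2, RMSE,
    Q2-LOO, Q2-F1/F2/F3, Lin's concordance correlation), Y-scrambling
    robustness testing, leverage-based applicability-domain (Williams
    plot) analysis, PCA-based model interpretation, seeded synthetic-data
    generators, and a grid runner that validates every combination of
    estimator, bandwidth method and kernel on a compound table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    KernSmooth,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
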