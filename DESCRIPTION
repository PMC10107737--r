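Package: cpmreserve
Title: Connectome-Based Predictive Modelling of Cognitive Reserve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building functional-connectivity matrices from node
    time series, constructing residual-based cognitive-reserve measures,
    and predicting them from connectome edges with connectome-based
    predictive modelling (CPM): mass-univariate edge selection with
    optional partial-correlation covariate adjustment, positive-,
    negative- and combined-network strength models, leave-one-out and
    repeated k-fold cross-validation, edge-selection-threshold
    optimisation, cross-dataset application of aggregated models,
    theoretical-validity testing (face validity, independence and
    moderation hierarchical regressions), selected-edge network anatomy
    summaries, and a seeded synthetic cohort generator with known ground
    truth for end-to-end parameter-recovery testing.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
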