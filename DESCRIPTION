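Package: survxplain
Title: Explainable Survival Machine Learning for Post-Surgery Mortality Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible workflow for modelling in-hospital
    mortality after surgery for congenital heart disease with survival machine
    learning and explaining the fitted models. The package simulates synthetic
    cohorts with the statistical structure of a paediatric heart-surgery
    registry (four disease groups, discharge-as-censoring, 72 h post-surgery
    laboratory series, missing-completely-at-random gaps), applies
    chained-equation imputation and clinical feature-engineering rules,
    builds stratified holdout splits and repeated cross-validation folds over
    follow-up time, event status and disease group, fits random survival
    forests, gradient-boosted Cox regression and Cox proportional hazards
    models behind a uniform risk-prediction contract, tunes hyperparameters
    with Gaussian-process Bayesian optimisation under an upper-confidence-bound
    acquisition, evaluates models with Harrell's concordance index, and
    computes per-model Shapley attributions and time-dependent SurvSHAP(t)
    curves together with their cross-model aggregates, rank-frequency and
    per-group force summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
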