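Package: stackprune
Title: Stacked Ensembles with Correlation-Based Classifier Removal for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("stackprune", "maintainers", email = "maintainers@stackprune.dev", role = c("aut", "cre"))
Description: Tools for binary clinical risk prediction on tabular registry
    cohorts using stacked generalization. A bank of heterogeneous base
    classifiers is tuned by random hyper-parameter search under repeated
    cross-validation with in-fold minority upsampling; base classifiers whose
    out-of-fold predictions are too correlated are pruned by an iterative
    removal scheme; a logistic meta-classifier is stacked on the survivors;
    and per-learner feature importances are combined by weighted-sum rank
    aggregation with a two-line knee-point cutoff. Includes a synthetic
    registry-cohort generator with planted linear, nonlinear and interaction
    signal so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    mgcv,
    MASS,
    FNN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
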