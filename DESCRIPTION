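Package: thermophen
Title: Thermal-Time Modelling of Olive Phenophases from Station and
    Reanalysis Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting ranked BBCH phenophases of olive trees
    from accumulated growing degree days (GDD). Computes daily and
    cumulative degree days from daily minimum/maximum temperatures by the
    simple-average and Allen single-sine methods, fits a per-phase
    mean-GDD threshold baseline model, wraps standard regression learners
    (linear models, CART, random forests, neural networks, gradient
    boosting) behind a uniform fit/predict contract with rank
    discretisation, evaluates models with stratified repeated train/test
    splits and the combined (1 - Accuracy) x RMSE metric, and optimises
    the base temperature by grid search with resampling confidence
    intervals. A synthetic-world generator emulates multi-location
    station and reanalysis-like daily temperature series with
    threshold-driven phenology so the whole pipeline can be exercised and
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    rpart,
    nnet,
    xgboost,
    jsonlite,
    optparse
Config/testthat/edition: 3
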