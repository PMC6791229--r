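Package: greycast
Title: Grey-Model and Hybrid Grey Machine-Learning Forecasting for Short Annual Incidence Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting tools for very short annual disease-incidence series
    built on grey systems theory. Implements five GM(1,1)-family grey models
    (the even grey model, its difference variants, the discrete grey model and
    the grey Verhulst model) fitted from first principles by least squares on
    the accumulated series, together with a two-stage hybrid scheme in which
    the grey fitted values become the feature matrix for second-stage machine
    learning regressors (k-nearest neighbours, support vector regression,
    random forests, gradient boosting and a single-hidden-layer neural
    network). Includes chronological train/test splitting, per-region
    normalization, forecast accuracy reports (ME, RMSE, MAE, MPE, MAPE), an
    exhaustive feature-subset search, synthetic series generators for property
    testing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    randomForest,
    xgboost,
    nnet,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
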