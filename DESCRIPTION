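Package: barncast
Title: Humidity Forecasting for Livestock Barns via GOSS Feature
    Selection and Chaotic Grey Wolf Optimised Support Vector Regression
Version: 0.1.0
Authors@R:
    person("Barncast", "Developers", email = "barncast@example.org",
           role = c("aut", "cre"))
Description: Short-horizon prediction of air humidity in intensive
    livestock housing from multivariate environmental sensor series.
    Implements gradient-boosted regression trees with gradient-based
    one-side sampling (GOSS) whose summed split gains rank and select
    influential microclimate covariates; a grey wolf optimizer and a
    chaotic variant with deterministic time-varying acceleration
    schedules for bound-constrained minimisation; an epsilon-insensitive
    support vector regression with radial basis kernel whose width
    parameter g enters the kernel as exp(-d2/g^2), tuned by the
    optimizer against forward-chaining cross-validated RMSE; evaluation
    metrics (MAE, RMSE, MSE, NRMSE, R2); a synthetic barn sensor table
    generator with a coupled humidity process; and an end-to-end
    repair/select/standardise/tune/evaluate pipeline with a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
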