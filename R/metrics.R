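#' Standardize a numeric column
#'
#' Centres and scales a vector to zero mean and unit *population* standard
#' deviation, `z = (x - mean(x)) / sd_pop(x)`. The population convention
#' (divide by `n`, not `n - 1`) is recorded in the returned parameters so the
#' round trip through [destandardize()] is exact.
#'
#' @param x numeric vector, at least 2 values, non-constant.
#' @param name optional column name used in error messages.
#' @return list with `values` (standardized vector) and `params`, a
#'   `standardization_params` object holding `mean` and `sd`.
#' @examples
#' s <- standardize(c(1, 2, 3))
#' s$values            # -1.224745 0 1.224745
#' destandardize(s$values, s$params)
#' @export
standardize <- function(x, name = "column") {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("standardize: '", name, "' needs at least 2 numeric values")
  }
  if (anyNA(x)) stop("standardize: '", name, "' contains missing values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s <= 0) stop("standardize: column '", name, "' is constant")
  params <- structure(list(mean = m, sd = s), class = "standardization_params")
  list(values = (x - m) / s, params = params)
}

#' Apply previously fitted standardization parameters
#'
#' Used to transform test data with parameters fitted on the training block
#' only, so no information leaks across the chronological split.
#'
#' @param x numeric vector.
#' @param params a `standardization_params` object from [standardize()].
#' @return standardized vector.
#' @export
standardize_apply <- function(x, params) {
  stopifnot(inherits(params, "standardization_params"))
  (x - params$mean) / params$sd
}

#' Invert a standardization
#'
#' @param z standardized values.
#' @param params a `standardization_params` object.
#' @return values on the original scale.
#' @export
destandardize <- function(z, params) {
  stopifnot(inherits(params, "standardization_params"))
  z * params$sd + params$mean
}

#' Forecast evaluation metrics
#'
#' Computes MAE, MSE, RMSE, NRMSE and R2 for a prediction against observed
#' values. NRMSE is RMSE divided by the mean of the observed series. R2 is
#' the explained-variance *ratio* `sum((pred - mean(actual))^2) /
#' sum((actual - mean(actual))^2)` — note this equals the conventional
#' `1 - SSres/SStot` only when residuals are orthogonal to the predictions
#' (e.g. an OLS fit); set `conventional_r2 = TRUE` to also report the
#' `1 - SSres/SStot` form.
#'
#' @param actual numeric vector of observed values (length >= 2).
#' @param predicted numeric vector of predictions, same length.
#' @param conventional_r2 also report `r2_conventional = 1 - SSres/SStot`.
#' @return a `metrics_report` object: list with `mae`, `rmse`, `mse`,
#'   `nrmse`, `r2` (and optionally `r2_conventional`).
#' @examples
#' evaluate_forecast(c(80, 80, 82, 82), c(79, 81, 81, 83))
#' @export
evaluate_forecast <- function(actual, predicted, conventional_r2 = FALSE) {
  if (length(actual) != length(predicted)) {
    stop("evaluate_forecast: actual and predicted lengths differ")
  }
  if (length(actual) < 2L) stop("evaluate_forecast: need at least 2 points")
  if (anyNA(actual) || anyNA(predicted) ||
      !all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop("evaluate_forecast: non-finite values")
  }
  fbar <- mean(actual)
  err <- actual - predicted
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  sstot <- sum((actual - fbar)^2)
  if (sstot <= 0) {
    stop("evaluate_forecast: zero-variance actual series, R2 undefined")
  }
  if (fbar == 0) stop("evaluate_forecast: mean(actual) is zero, NRMSE undefined")
  rep <- list(
    mae = mean(abs(err)),
    rmse = rmse,
    mse = mse,
    nrmse = rmse / fbar,
    r2 = sum((predicted - fbar)^2) / sstot
  )
  if (conventional_r2) rep$r2_conventional <- 1 - sum(err^2) / sstot
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE %.4f  RMSE %.4f  MSE %.4f  NRMSE %.4f  R2 %.4f\n",
              x$mae, x$rmse, x$mse, x$nrmse, x$r2))
  invisible(x)
}

#' Serialize a metrics report to one CSV row
#'
#' Column order MAE, RMSE, MSE, NRMSE, R2.
#'
#' @param report a `metrics_report`.
#' @param path output file path.
#' @param model optional model label prepended as first column.
#' @export
write_metrics_csv <- function(report, path, model = NULL) {
  df <- data.frame(MAE = report$mae, RMSE = report$rmse, MSE = report$mse,
                   NRMSE = report$nrmse, R2 = report$r2)
  if (!is.null(model)) df <- cbind(data.frame(model = model), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
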