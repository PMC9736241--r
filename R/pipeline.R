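#' Repair a sensor table
#'
#' Fills missing values and physically impossible readings (humidity outside
#' \[0, 100\], negative concentrations/light/noise) by linear interpolation
#' between the nearest valid neighbours; boundary gaps take the nearest
#' valid value. Errors if more than 20% of any column needs repair.
#'
#' @param table a sensor table with sorted timestamps.
#' @return the repaired table, with attribute `n_repaired` (total cells
#'   fixed).
#' @export
repair_table <- function(table) {
  if (!"timestamp" %in% names(table)) stop("repair_table: no timestamp column")
  if (is.unsorted(table$timestamp, strictly = TRUE)) {
    stop("repair_table: timestamps must be strictly increasing")
  }
  n <- nrow(table)
  total <- 0L
  for (col in setdiff(names(table), "timestamp")) {
    v <- table[[col]]
    bad <- is.na(v) | !is.finite(v) | v < 0
    if (col == "air_humidity") bad <- bad | (!is.na(v) & v > 100)
    nb <- sum(bad)
    if (nb == 0L) next
    if (nb > 0.2 * n) {
      stop("repair_table: column '", col, "' has more than 20% invalid values")
    }
    good <- which(!bad)
    v[bad] <- stats::approx(good, v[good], xout = which(bad),
                            method = "linear", rule = 2)$y
    table[[col]] <- v
    total <- total + nb
  }
  attr(table, "n_repaired") <- total
  table
}

#' Build a lagged forecast dataset
#'
#' Pairs the feature values at time `t` (optionally plus current humidity)
#' with humidity at time `t + horizon`, so every input strictly precedes its
#' target; one step equals the 10-minute sampling interval.
#'
#' @param table a (repaired) sensor table.
#' @param features character vector of feature column names.
#' @param horizon forecast horizon in steps (>= 1).
#' @param include_target_lag also include current humidity as an input.
#' @return a `forecast_dataset`: list with `inputs` (matrix), `targets`,
#'   `horizon`, `feature_names`.
#' @export
build_forecast_dataset <- function(table, features, horizon = 1,
                                   include_target_lag = FALSE) {
  if (horizon < 1 || horizon >= nrow(table)) {
    stop("build_forecast_dataset: horizon out of range")
  }
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0) {
    stop("build_forecast_dataset: unknown feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  idx <- seq_len(n - horizon)
  x <- as.matrix(table[idx, features, drop = FALSE])
  rownames(x) <- NULL
  if (include_target_lag) {
    x <- cbind(x, humidity_lag = table$air_humidity[idx])
  }
  structure(list(inputs = x, targets = table$air_humidity[idx + horizon],
                 horizon = horizon, feature_names = colnames(x)),
            class = "forecast_dataset")
}

subset_dataset <- function(dataset, rows) {
  structure(list(inputs = dataset$inputs[rows, , drop = FALSE],
                 targets = dataset$targets[rows],
                 horizon = dataset$horizon,
                 feature_names = dataset$feature_names),
            class = "forecast_dataset")
}

#' Chronological train/test split
#'
#' First `floor(train_frac * n)` rows become the training set, the remainder
#' the test set; no shuffling, preserving temporal order.
#'
#' @param dataset a `forecast_dataset`.
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @return list with `train` and `test` forecast datasets.
#' @export
chronological_split <- function(dataset, train_frac = 0.7) {
  n <- length(dataset$targets)
  if (n < 10) stop("chronological_split: need at least 10 rows")
  n_train <- floor(train_frac * n)
  if (n_train < 1 || n_train >= n) {
    stop("chronological_split: split leaves an empty side")
  }
  list(train = subset_dataset(dataset, seq_len(n_train)),
       test = subset_dataset(dataset, (n_train + 1L):n))
}

#' Pipeline configuration
#'
#' @param input path to a sensor CSV, or a data.frame; `NULL` generates a
#'   synthetic table of `n_rows` records.
#' @param n_rows rows for synthetic generation when `input` is `NULL`.
#' @param k_features number of features kept by importance selection.
#' @param horizon forecast horizon in 10-minute steps (1, 3, 6 or 9 for the
#'   10/30/60/90-minute settings; any value >= 1 is accepted).
#' @param train_frac chronological training fraction.
#' @param pack_size,max_iter,variant optimizer settings.
#' @param folds forward-chaining CV folds for the tuning fitness.
#' @param include_target_lag add current humidity to the inputs.
#' @param baselines subset of `c("svr_default", "gwo")` to run alongside.
#' @param goss a [goss_config()].
#' @param seed integer seed making the whole run reproducible.
#' @param outdir optional directory for CSV artifacts and a log.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, n_rows = 2000, k_features = 4,
                            horizon = 1, train_frac = 0.7, pack_size = 20,
                            max_iter = 20, variant = "cgwo", folds = 5,
                            include_target_lag = FALSE,
                            baselines = "svr_default",
                            goss = goss_config(), seed = 1, outdir = NULL) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("pipeline_config: train_frac must lie in (0, 1)")
  }
  if (horizon < 1) stop("pipeline_config: horizon must be >= 1")
  if (!all(baselines %in% c("svr_default", "gwo"))) {
    stop("pipeline_config: unknown baseline")
  }
  structure(list(input = input, n_rows = n_rows, k_features = k_features,
                 horizon = horizon, train_frac = train_frac,
                 pack_size = pack_size, max_iter = max_iter, variant = variant,
                 folds = folds, include_target_lag = include_target_lag,
                 baselines = baselines, goss = goss, seed = seed,
                 outdir = outdir),
            class = "pipeline_config")
}

evaluate_model <- function(train, test, params) {
  pred <- fit_predict_svr(train$inputs, train$targets, test$inputs, params)
  list(params = params, predictions = pred,
       metrics = evaluate_forecast(test$targets, pred))
}

#' Run the full humidity-forecasting pipeline
#'
#' The five-stage method: (1) repair the table, (2) rank features by GOSS
#' split gain on the training block and keep the top k, (3) standardize with
#' training-block parameters and split 70/30 chronologically, (4) tune
#' (C, g, eps) in the `[0.01, 10]^3` box by the chaotic grey wolf optimizer
#' against forward-chaining CV RMSE on the training block, (5) fit the tuned
#' SVR and evaluate on the held-out block in original humidity units.
#' Requested baselines (untuned SVR with C=1, g=0.1, eps=0.1; canonical GWO
#' tuning) run on the same split. The run is a pure function of
#' (input, config, seed).
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list: `importance`, `selected_features`,
#'   `best_params`, `best_fitness`, `trace`, `models` (per-model params,
#'   predictions and `metrics_report`), `n_repaired`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # stage 1: acquire + repair
  table <- if (is.null(config$input)) {
    generate_barn_data(config$n_rows)
  } else if (is.character(config$input)) {
    read_sensor_csv(config$input)
  } else {
    config$input
  }
  table <- tryCatch(repair_table(table),
                    error = function(e) stop("stage repair: ", conditionMessage(e)))
  say("repair: %d cells fixed", attr(table, "n_repaired"))

  # stage 2: importance on the training block only, then top-k selection
  all_feats <- intersect(sensor_feature_names(), names(table))
  full <- build_forecast_dataset(table, all_feats, config$horizon,
                                 include_target_lag = FALSE)
  split_full <- chronological_split(full, config$train_frac)
  goss_fit <- tryCatch(
    fit_goss_gbdt(split_full$train$inputs, split_full$train$targets,
                  config$goss),
    error = function(e) stop("stage importance: ", conditionMessage(e)))
  importance <- goss_fit$importance
  selected <- select_features(importance, config$k_features)
  say("selected features: %s", paste(selected, collapse = ", "))

  # stage 3: lagged dataset on the selected features, chronological split
  dataset <- build_forecast_dataset(table, selected, config$horizon,
                                    config$include_target_lag)
  split <- chronological_split(dataset, config$train_frac)
  train <- split$train
  test <- split$test

  # stage 4: hyperparameter search on standardized training data
  xs <- matrix(0, nrow(train$inputs), ncol(train$inputs))
  for (j in seq_len(ncol(train$inputs))) {
    xs[, j] <- standardize(train$inputs[, j],
                           name = colnames(train$inputs)[j])$values
  }
  ys <- standardize(train$targets, name = "air_humidity")$values
  objective <- make_cv_objective(xs, ys, folds = config$folds)
  space <- search_space(rep(0.01, 3), rep(10, 3))
  opt <- tryCatch(
    gwo_optimize(objective, space, pack_size = config$pack_size,
                 max_iter = config$max_iter, variant = config$variant),
    error = function(e) stop("stage tune: ", conditionMessage(e)))
  best_params <- decode_position(opt$best_position)
  say("tuned %s: C=%.4f g=%.4f eps=%.4f (cv fitness %.5f)", config$variant,
      best_params$C, best_params$g, best_params$eps, opt$best_fitness)

  # stage 5: final fit + held-out evaluation in original units
  models <- list()
  models[[paste0(config$variant, "_svr")]] <-
    evaluate_model(train, test, best_params)
  if ("svr_default" %in% config$baselines) {
    models$svr_default <- evaluate_model(train, test, svr_params(1, 0.1, 0.1))
  }
  if ("gwo" %in% config$baselines && config$variant != "gwo") {
    opt_gwo <- gwo_optimize(objective, space, pack_size = config$pack_size,
                            max_iter = config$max_iter, variant = "gwo")
    models$gwo_svr <- evaluate_model(train, test,
                                     decode_position(opt_gwo$best_position))
  }
  for (nm in names(models)) {
    m <- models[[nm]]$metrics
    say("%s: MAE %.4f RMSE %.4f MSE %.4f NRMSE %.5f R2 %.4f",
        nm, m$mae, m$rmse, m$mse, m$nrmse, m$r2)
  }

  report <- structure(
    list(importance = importance, selected_features = selected,
         best_params = best_params, best_fitness = opt$best_fitness,
         trace = opt$trace, models = models,
         n_repaired = attr(table, "n_repaired"),
         log = log_lines, config = config),
    class = "pipeline_report")
  if (!is.null(config$outdir)) write_pipeline_artifacts(report, test)
  report
}

write_pipeline_artifacts <- function(report, test) {
  dir.create(report$config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(report$config$outdir, f)
  write_importance_csv(report$importance, out("importance.csv"))
  utils::write.csv(data.frame(C = report$best_params$C,
                              g = report$best_params$g,
                              epsilon = report$best_params$eps),
                   out("hyperparameters.csv"), row.names = FALSE)
  metrics_df <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]$metrics
    data.frame(model = nm, MAE = m$mae, RMSE = m$rmse, MSE = m$mse,
               NRMSE = m$nrmse, R2 = m$r2)
  }))
  utils::write.csv(metrics_df, out("metrics.csv"), row.names = FALSE)
  utils::write.csv(report$trace, out("trace.csv"), row.names = FALSE)
  pred_df <- data.frame(actual = test$targets)
  for (nm in names(report$models)) pred_df[[nm]] <- report$models[[nm]]$predictions
  utils::write.csv(pred_df, out("predictions.csv"), row.names = FALSE)
  writeLines(report$log, out("log.txt"))
  invisible(report$config$outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("humidity forecasting pipeline (horizon", x$config$horizon, "steps)\n")
  cat("selected features:", paste(x$selected_features, collapse = ", "), "\n")
  cat(sprintf("tuned hyperparameters: C=%.4f g=%.4f eps=%.4f\n",
              x$best_params$C, x$best_params$g, x$best_params$eps))
  for (nm in names(x$models)) {
    cat(sprintf("%-14s", nm)); print(x$models[[nm]]$metrics)
  }
  invisible(x)
}
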