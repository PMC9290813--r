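#' Forecast model specification
#'
#' Fixes the response (cube root of reflectivity times groundspeed), the 13
#' predictors, and the tree-booster hyperparameters: `max_depth = 12`,
#' `eta = 0.01`, `gamma = 1`, `colsample_bytree = 1`,
#' `min_child_weight = 5`, `subsample = 0.7`. With such a small learning
#' rate many rounds are needed; `n_rounds` caps them and early stopping on a
#' 10% random tuning split halts training once the tuning error stops
#' improving.
#'
#' @param season `"spring"` or `"autumn"`.
#' @param training_years Integer years used for training.
#' @param holdout_year Optional held-out year; must not intersect
#'   `training_years`.
#' @param n_rounds Maximum boosting rounds (>= 1). Default 1000.
#' @param early_stopping_rounds Patience, rounds. Default 50.
#' @param tuning_fraction Fraction of training rows used as the tuning
#'   split. Default 0.1.
#' @param max_train_rows Cap on training rows (random subsample when
#'   exceeded); `Inf` disables. Default `Inf`.
#' @param seed Integer seed for subsampling and the booster.
#' @return A `forecast_spec` list.
#' @export
forecast_spec <- function(season = c("spring", "autumn"),
                          training_years,
                          holdout_year = NULL,
                          n_rounds = 1000L,
                          early_stopping_rounds = 50L,
                          tuning_fraction = 0.1,
                          max_train_rows = Inf,
                          seed = 1L) {
  season <- match.arg(season)
  training_years <- as.integer(training_years)
  stopifnot(length(training_years) >= 1L, n_rounds >= 1L,
            tuning_fraction > 0, tuning_fraction < 1)
  if (length(holdout_year) == 0L || all(is.na(holdout_year)))
    holdout_year <- NULL
  if (!is.null(holdout_year) && holdout_year %in% training_years)
    stop("validation error: holdout_year must not be in training_years")
  structure(
    list(season = season, training_years = training_years,
         holdout_year = holdout_year,
         params = list(max_depth = 12, eta = 0.01, gamma = 1,
                       colsample_bytree = 1, min_child_weight = 5,
                       subsample = 0.7, objective = "reg:squarederror",
                       nthread = 1),
         n_rounds = as.integer(n_rounds),
         early_stopping_rounds = as.integer(early_stopping_rounds),
         tuning_fraction = tuning_fraction,
         max_train_rows = max_train_rows, seed = as.integer(seed)),
    class = "forecast_spec")
}

features_year <- function(features) as.integer(format(features$night_id, "%Y"))

#' Variance explained
#'
#' `1 - SSE/SST`, with SST about the mean of the observations. Equals 1 for
#' a perfect predictor and 0 for the constant-mean predictor.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Scalar variance explained.
#' @export
variance_explained <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  1 - sum((observed - predicted)^2) /
    sum((observed - mean(observed))^2)
}

#' Train a seasonal gradient-boosted forecast model
#'
#' Restricts the feature table to the spec's training years, asserts the
#' held-out year is absent (leakage check), carves out a random tuning
#' split, and fits the booster with early stopping. Reproducible given the
#' spec's seed.
#'
#' @param features Feature table from [build_features()].
#' @param spec A [forecast_spec()].
#' @return A `seasonal_model` list: `booster` (xgboost handle),
#'   `feature_names` (the contract order), `spec`, `best_iteration`.
#' @export
train_seasonal_model <- function(features, spec) {
  stopifnot(inherits(spec, "forecast_spec"))
  f <- as.data.table(features)
  f <- f[features_year(f) %in% spec$training_years]
  if (nrow(f) == 0L) stop("training error: empty training set")
  if (!is.null(spec$holdout_year) &&
      any(features_year(f) == spec$holdout_year))
    stop("leakage: held-out year present in training rows")

  set.seed(derive_seed(spec$seed, 4L))
  if (is.finite(spec$max_train_rows) && nrow(f) > spec$max_train_rows)
    f <- f[sample.int(nrow(f), spec$max_train_rows)]
  n <- nrow(f)
  tune_idx <- sample.int(n, max(1L, round(spec$tuning_fraction * n)))
  cols <- feature_columns()
  dtrain <- xgboost::xgb.DMatrix(as.matrix(f[-tune_idx, ..cols]),
                                 label = f$response[-tune_idx], nthread = 1)
  dtune <- xgboost::xgb.DMatrix(as.matrix(f[tune_idx, ..cols]),
                                label = f$response[tune_idx], nthread = 1)
  params <- c(spec$params, list(seed = derive_seed(spec$seed, 5L)))
  booster <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = spec$n_rounds,
    evals = list(tune = dtune),
    early_stopping_rounds = spec$early_stopping_rounds, verbose = 0
  )
  best <- xgboost::xgb.attr(booster, "best_iteration")
  structure(
    list(booster = booster, feature_names = cols, spec = spec,
         best_iteration = if (is.null(best)) spec$n_rounds
                          else as.integer(best)),
    class = "seasonal_model")
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat("<seasonal_model> ", x$spec$season, ", trained on years ",
      paste(x$spec$training_years, collapse = ", "), "; best iteration ",
      x$best_iteration, "\n", sep = "")
  invisible(x)
}

#' Predict the 30-min response for a feature table
#'
#' @param model A `seasonal_model`.
#' @param features Feature table (response column not required).
#' @return Numeric vector of predicted cube-root-scale responses, in the
#'   row order of `features`.
#' @export
predict_response <- function(model, features) {
  stopifnot(inherits(model, "seasonal_model"))
  f <- as.data.table(features)
  cols <- model$feature_names
  miss <- setdiff(cols, names(f))
  if (length(miss) > 0L)
    stop("validation error: features lack column(s): ",
         paste(miss, collapse = ", "))
  predict(model$booster, xgboost::xgb.DMatrix(as.matrix(f[, ..cols]),
                                              nthread = 1))
}

#' Predict nightly migration traffic
#'
#' Predicts the 30-min cube-root-scale response, back-transforms by cubing
#' (flooring at 0 after the back-transform), and integrates the predicted
#' rates over each night with the same trapezoid / bin-height /
#' cross-section chain as [integrate_night()].
#'
#' @param model A `seasonal_model`.
#' @param features Feature table for the nights to predict (typically built
#'   from the forecast weather channel).
#' @param cross_section Radar cross-section, cm^2. Default 11.
#' @param bin_height Bin height, km. Default 0.1.
#' @return `data.table`: `station_id`, `night_id`, `predicted_traffic`
#'   (birds/km/night). Nights with fewer than 2 time steps are omitted with
#'   a message.
#' @export
predict_nightly <- function(model, features, cross_section = 11,
                            bin_height = 0.1) {
  f <- as.data.table(features)
  pred_rate <- pmax(predict_response(model, f), 0)^3 # cm^2/km^2/h
  pseudo <- f[, .(station_id, night_id, minutes_after_sunset,
                  height_bin_m)]
  pseudo[, `:=`(eta_cm2_per_km3 = pred_rate, groundspeed_kmh = 1)]
  nightly <- integrate_core(pseudo, cross_section, bin_height,
                            gap_fill = "interpolate")
  dropped <- nightly[n_samples < 2L]
  if (nrow(dropped) > 0L)
    message("predict_nightly: omitted ", nrow(dropped),
            " night(s) with fewer than 2 time steps")
  nightly[n_samples >= 2L,
          .(station_id, night_id, predicted_traffic = traffic)]
}

#' Leave-one-year-out evaluation
#'
#' For each year, trains a seasonal model on all other years, predicts the
#' held-out year from forecast-channel covariates, and reports variance
#' explained (1 - SSE/SST) on the cube-root 30-min scale together with the
#' nightly-scale Pearson correlation between predicted and measured
#' traffic.
#'
#' Forecast error only enters at prediction time (models are always trained
#' on the reanalysis channel), so the returned models can be re-applied to
#' alternative forecast feature tables.
#'
#' @param features Feature table built from the reanalysis weather channel.
#' @param forecast_features Feature table built from the forecast channel;
#'   defaults to `features` (the idealized, zero-forecast-error limit).
#' @param nightly Measured nightly traffic table (for the nightly-scale
#'   correlation); `NULL` computes it from the observed responses.
#' @param season `"spring"` or `"autumn"`.
#' @param n_rounds,max_train_rows,seed Passed to [forecast_spec()].
#' @param keep_models Keep the per-fold boosters in the result. Default
#'   `FALSE`.
#' @return A `loyo_result` list: `per_year` (`data.table`: `year`,
#'   `r2_sample`, `nightly_cor`, `n_rows`, `n_nights`), `mean_r2`, `sd_r2`,
#'   `predictions` (nightly predictions for every held-out station-night),
#'   and optionally `models` (named by held-out year).
#' @export
loyo_evaluate <- function(features, forecast_features = NULL, nightly = NULL,
                          season = c("spring", "autumn"), n_rounds = 1000L,
                          max_train_rows = Inf, seed = 1L,
                          keep_models = FALSE) {
  season <- match.arg(season)
  f <- as.data.table(features)
  ff <- if (is.null(forecast_features)) f else as.data.table(forecast_features)
  yrs <- sort(unique(features_year(f)))
  if (length(yrs) < 2L)
    stop("validation error: leave-one-year-out needs at least 2 years")
  if (is.null(nightly)) {
    obs <- copy(f)
    obs[, `:=`(eta_cm2_per_km3 = response^3, groundspeed_kmh = 1)]
    nightly <- integrate_core(obs, 11, 0.1, "interpolate")
  }
  nightly <- as.data.table(nightly)

  per_year <- list(); preds <- list(); models <- list()
  fy <- features_year(f)
  ffy <- features_year(ff)
  for (i in seq_along(yrs)) {
    y <- yrs[i]
    spec <- forecast_spec(season = season, training_years = setdiff(yrs, y),
                          holdout_year = y, n_rounds = n_rounds,
                          max_train_rows = max_train_rows,
                          seed = derive_seed(seed, 100L + i))
    train <- f[fy != y]
    hold <- ff[ffy == y]
    leak <- intersect(paste(train$station_id, train$night_id),
                      paste(hold$station_id, hold$night_id))
    if (length(leak) > 0L)
      stop("leakage: training and held-out sets share station-nights")
    model <- train_seasonal_model(train, spec)

    p <- predict_response(model, hold)
    r2 <- variance_explained(hold$response, p)

    np <- predict_nightly(model, hold)
    m <- nightly[np, on = c("station_id", "night_id")]
    m <- m[complete == TRUE]
    ncor <- if (nrow(m) >= 3L) cor(m$predicted_traffic, m$traffic)
            else NA_real_
    per_year[[i]] <- data.table(year = y, r2_sample = r2, nightly_cor = ncor,
                                n_rows = nrow(hold), n_nights = nrow(np))
    preds[[i]] <- np[, c(list(year = y), .SD)]
    if (keep_models) models[[as.character(y)]] <- model
  }
  per_year <- rbindlist(per_year)
  structure(
    list(per_year = per_year, mean_r2 = mean(per_year$r2_sample),
         sd_r2 = sd(per_year$r2_sample), predictions = rbindlist(preds),
         models = if (keep_models) models else NULL),
    class = "loyo_result")
}

#' @export
print.loyo_result <- function(x, ...) {
  cat("<loyo_result> ", nrow(x$per_year), " folds; variance explained ",
      sprintf("%.3f (SD %.3f)", x$mean_r2, x$sd_r2), " on the cube-root ",
      "30-min scale\n", sep = "")
  print(x$per_year)
  invisible(x)
}

#' Save / load a model artifact with its manifest
#'
#' The manifest records hyperparameters, training years, seed and the
#' feature order; the feature order is part of the contract and is checked
#' at load.
#'
#' @param model A `seasonal_model`.
#' @param dir Output directory.
#' @return `save_model`: invisibly, the manifest list. `load_model`: the
#'   restored `seasonal_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "seasonal_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  manifest <- list(
    feature_names = model$feature_names,
    params = model$spec$params,
    training_years = model$spec$training_years,
    holdout_year = model$spec$holdout_year,
    n_rounds = model$spec$n_rounds, seed = model$spec$seed,
    season = model$spec$season, best_iteration = model$best_iteration
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(as.character(man$feature_names), feature_columns()))
    stop("validation error: model manifest feature order does not match ",
         "the package contract")
  booster <- xgboost::xgb.load(file.path(dir, "booster.ubj"))
  spec <- forecast_spec(season = man$season,
                        training_years = man$training_years,
                        holdout_year = man$holdout_year,
                        n_rounds = man$n_rounds, seed = man$seed)
  structure(list(booster = booster, feature_names = feature_columns(),
                 spec = spec, best_iteration = man$best_iteration),
            class = "seasonal_model")
}
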