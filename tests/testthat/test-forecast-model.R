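# minimal weather table for join tests: given UTC timestamps and vwind
# values at height 0, all other covariates constant
toy_weather <- function(ts, vwind, station = "KTST") {
  data.table(
    station_id = station, timestamp_utc = as.POSIXct(ts, tz = "UTC"),
    height_m = 0, uwind_ms = 1, vwind_ms = vwind, temp_c = 10,
    sp_pa = 101325, rh_pct = 50, tcc_pct = 20, vis_m = 10000,
    mslp_pa = 101325
  )
}

toy_profile <- function(minutes, eta = 8, speed = 27, station = "KTST",
                        night = as.Date("2015-04-01")) {
  data.table(
    station_id = station, latitude = 40, longitude = -90,
    night_id = night, minutes_after_sunset = as.integer(minutes),
    height_bin_m = 0L, eta_cm2_per_km3 = eta, groundspeed_kmh = speed,
    direction_deg = 0
  )
}

# a feature table that looks like build_features() output, with response
# supplied by `f` of the features; nights split across years
synth_features <- function(n, years, f, seed = 1) {
  set.seed(seed)
  starts <- as.Date(sprintf("%d-03-01", years))
  night_id <- sample(unlist(lapply(starts, `+`, 0:101)), n, replace = TRUE)
  ft <- data.table(
    station_id = "KTST", night_id = as.Date(night_id, origin = "1970-01-01"),
    minutes_after_sunset = sample(seq(0L, 600L, 30L), n, TRUE),
    height_bin_m = sample(seq(0L, 2900L, 100L), n, TRUE),
    latitude = 40, longitude = -90,
    uwind_ms = rnorm(n, 3, 2), vwind_ms = rnorm(n, 0, 4),
    temp_c = rnorm(n, 10, 5), sp_pa = rnorm(n, 101325, 300),
    rh_pct = runif(n, 0, 100), tcc_pct = runif(n, 0, 100),
    vis_m = runif(n, 0, 2e4), mslp_pa = rnorm(n, 101325, 300)
  )
  ft[, height_m := as.numeric(height_bin_m)]
  ft[, ordinal_date := as.integer(format(night_id, "%j"))]
  ft[, hour_after_sunset := minutes_after_sunset / 60]
  ft[, response := f(ft)]
  ft[]
}

test_that("samples join the weather record nearest in time", {
  # station at -90 deg: sunset = 01:00 UTC of the next day
  wx <- toy_weather(c("2015-04-02 00:00:00", "2015-04-02 03:00:00"),
                    vwind = c(-5, 5))
  st <- list(station_config("KTST", 40, -90))
  # sample at 01:10 UTC: 70 min from 00:00, 110 from 03:00 -> earlier
  f <- build_features(toy_profile(10), wx, st)
  expect_equal(f$vwind_ms, -5)
  # equidistant sample at 01:30 UTC: tie broken toward the earlier record
  f2 <- build_features(toy_profile(30), wx, st)
  expect_equal(f2$vwind_ms, -5)
  # past the midpoint the later record wins
  f3 <- build_features(toy_profile(31), wx, st)
  expect_equal(f3$vwind_ms, 5)
})

test_that("the response is the cube root of reflectivity times speed", {
  wx <- toy_weather("2015-04-02 00:00:00", vwind = 0)
  st <- list(station_config("KTST", 40, -90))
  f <- build_features(toy_profile(0, eta = 8, speed = 27), wx, st)
  expect_equal(f$response, 6) # (8 * 27)^(1/3)
  expect_equal(f$hour_after_sunset, 0) # sample at sunset
  expect_identical(ncol(f[, .SD, .SDcols = aeroalert:::feature_columns()]),
                   13L)
})

test_that("samples with no weather within 3 h are dropped with a message", {
  wx <- toy_weather("2015-04-01 12:00:00", vwind = 0)
  st <- list(station_config("KTST", 40, -90))
  # sunset is 01:00 UTC on Apr 2: 13 h from the only weather record
  expect_message(f <- build_features(toy_profile(0), wx, st), "dropped")
  expect_equal(nrow(f), 0L)
})

test_that("variance explained is 1 for perfect and 0 for mean predictions", {
  obs <- c(1, 4, 2, 8, 5)
  expect_equal(variance_explained(obs, obs), 1.0)
  expect_equal(variance_explained(obs, rep(mean(obs), 5)), 0.0)
})

test_that("a constant response trains to constant predictions", {
  ft <- synth_features(500, 2014:2015, function(x) rep(0, nrow(x)))
  spec <- forecast_spec("spring", training_years = 2014:2015, n_rounds = 5)
  m <- train_seasonal_model(ft, spec)
  expect_lt(max(abs(predict_response(m, ft))), 1e-6)
  # identical features give identical predictions
  expect_identical(predict_response(m, ft[1:10]),
                   predict_response(m, ft[1:10]))
})

test_that("the booster recovers a monotone single-predictor signal", {
  f_gen <- function(x) 5 / (1 + exp(-x$vwind_ms / 3))
  ft <- synth_features(10000, 2014:2015, f_gen, seed = 2)
  spec <- forecast_spec("spring", training_years = 2014,
                        holdout_year = 2015, n_rounds = 400, seed = 3)
  m <- train_seasonal_model(ft, spec)
  hold <- ft[format(night_id, "%Y") == "2015"]
  r2 <- variance_explained(hold$response, predict_response(m, hold))
  expect_gte(r2, 0.95)
  # permuting a predictor absent from the generating function barely moves
  # held-out skill
  perm <- copy(hold)
  set.seed(4)
  perm[, rh_pct := sample(rh_pct)]
  r2_perm <- variance_explained(perm$response, predict_response(m, perm))
  expect_lt(abs(r2 - r2_perm), 0.02)
})

test_that("back-transformed constant predictions integrate in closed form", {
  ft <- synth_features(2000, 2014:2015, function(x) rep(2, nrow(x)))
  spec <- forecast_spec("spring", training_years = 2014:2015, n_rounds = 5)
  m <- train_seasonal_model(ft, spec)
  # one full 10-h, 30-bin night of features
  night <- CJ(minutes_after_sunset = seq(0L, 600L, 30L),
              height_bin_m = seq(0L, 2900L, 100L))
  night[, `:=`(station_id = "KTST", night_id = as.Date("2015-04-01"),
               latitude = 40, longitude = -90,
               height_m = as.numeric(height_bin_m),
               ordinal_date = 91L,
               hour_after_sunset = minutes_after_sunset / 60,
               uwind_ms = 1, vwind_ms = 1, temp_c = 10, sp_pa = 101325,
               rh_pct = 50, tcc_pct = 20, vis_m = 10000, mslp_pa = 101325)]
  p <- predict_nightly(m, night)
  # response r = 2 everywhere: traffic = r^3 x 10 h x 0.1 km x 30 bins / 11
  expect_equal(p$predicted_traffic, 2^3 * 10 * 0.1 * 30 / 11,
               tolerance = 1e-6)
  # cube / cube-root round trip at float precision
  r <- c(0.3, 2, 17.5)
  expect_equal((r^3)^(1 / 3), r, tolerance = 1e-9)
})

test_that("training refuses leakage from the held-out year", {
  expect_error(forecast_spec("spring", training_years = 2014:2016,
                             holdout_year = 2015),
               "holdout_year")
  ft <- synth_features(300, 2014:2015, function(x) rnorm(nrow(x)))
  spec <- forecast_spec("spring", training_years = 2014,
                        holdout_year = 2015, n_rounds = 2)
  # force the holdout year into the training filter via a doctored spec
  spec$training_years <- 2014:2015
  expect_error(train_seasonal_model(ft, spec), "leakage")
})

test_that("model artifacts round-trip through save/load with the manifest", {
  ft <- synth_features(500, 2014:2015, function(x) x$vwind_ms)
  spec <- forecast_spec("spring", training_years = 2014:2015, n_rounds = 10)
  m <- train_seasonal_model(ft, spec)
  dir <- file.path(tempdir(), "model_artifact")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(predict_response(m2, ft[1:50]),
               predict_response(m, ft[1:50]))
  # a manifest with reordered features is refused
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$feature_names <- rev(man$feature_names)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir), "feature order")
  unlink(dir, recursive = TRUE)
})
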