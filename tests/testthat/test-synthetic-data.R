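one_station_cfg <- function(...) {
  sim_config(list(station_config("KAAA", 40, -90, night_length = 8)),
             years = 2015, season = "spring", ...)
}

test_that("generator output is a pure function of (config, seed)", {
  cfg <- one_station_cfg(seed = 9)
  w1 <- simulate_weather(cfg); w2 <- simulate_weather(cfg)
  expect_identical(w1, w2)
  m1 <- simulate_migration(cfg, w1); m2 <- simulate_migration(cfg, w2)
  expect_identical(m1$profiles, m2$profiles)
  expect_identical(m1$truth, m2$truth)
  # a different seed changes the draw
  w3 <- simulate_weather(one_station_cfg(seed = 10))
  expect_false(identical(w1$vwind_ms, w3$vwind_ms))
})

test_that("weather grid has one record per station x timestamp x level", {
  cfg <- one_station_cfg(seed = 2)
  w <- simulate_weather(cfg)
  # 102 nights x 8 three-hour timestamps x 31 levels
  expect_equal(nrow(w), 102 * 8 * 31)
  expect_false(anyDuplicated(w, by = c("station_id", "timestamp_utc",
                                       "height_m")) > 0)
  expect_true(all(w$rh_pct >= 0 & w$rh_pct <= 100))
  expect_true(all(w$tcc_pct >= 0 & w$tcc_pct <= 100))
  expect_true(all(w$vis_m >= 0))
})

test_that("rho = 0 gives serially uncorrelated nightly mean winds", {
  cfg <- sim_config(list(station_config("KAAA", 40, -90, night_length = 8)),
                    years = 2013:2017, season = "spring",
                    weather_ar1_rho = 0, seed = 4)
  w <- simulate_weather(cfg)
  w[, night_id := night_of_timestamp(timestamp_utc, -90)]
  nightly <- w[, .(v = mean(vwind_ms)), keyby = night_id]
  nightly[, year := format(night_id, "%Y")]
  # pool lag-1 pairs within years: > 500 nights in total
  pairs <- nightly[, .(a = head(v, -1), b = tail(v, -1)), by = year]
  expect_gt(nrow(pairs), 490)
  expect_lt(abs(cor(pairs$a, pairs$b)), 0.1)
})

test_that("with all noise off nightly totals follow the closed-form envelope", {
  cfg <- one_station_cfg(pulse_beta = 0, pulse_sigma = 0, obs_sigma = 0,
                         phenology_jitter_sd = 0, dropout_rate = 0, seed = 3)
  mig <- simulate_migration(cfg, simulate_weather(cfg))
  nightly <- integrate_profiles(mig$profiles)
  chk <- merge(nightly, mig$truth, by = c("station_id", "night_id"))
  # integration recovers latent_total / cross-section to float precision
  expect_lt(max(abs(chk$traffic - chk$latent_total / 11) /
                  pmax(chk$latent_total / 11, 1e-12)), 1e-6)
  # ratio of peak night to peak + 1 sd night totals = exp(0.5)
  ords <- as.integer(format(chk$night_id, "%j"))
  t_mu <- chk$traffic[ords == cfg$phenology_peak_mu]
  t_mu_sd <- chk$traffic[ords == cfg$phenology_peak_mu + cfg$phenology_sd]
  expect_equal(t_mu / t_mu_sd, exp(0.5), tolerance = 1e-6)
})

test_that("zero envelope amplitude silences every sample and total", {
  cfg <- one_station_cfg(envelope_amplitude = 0, dropout_rate = 0, seed = 5)
  mig <- simulate_migration(cfg, simulate_weather(cfg))
  expect_true(all(mig$profiles$eta_cm2_per_km3 == 0))
  expect_true(all(mig$truth$latent_total == 0))
  nightly <- integrate_profiles(mig$profiles)
  expect_true(all(nightly$traffic == 0))
})

test_that("reflectivity, speed and totals are non-negative everywhere", {
  cfg <- one_station_cfg(seed = 6)
  mig <- simulate_migration(cfg, simulate_weather(cfg))
  expect_true(all(mig$profiles$eta_cm2_per_km3 >= 0))
  expect_true(all(mig$profiles$groundspeed_kmh >= 1))
  expect_true(all(mig$truth$latent_total >= 0))
})

test_that("invalid configurations are rejected", {
  st <- list(station_config("KAAA", 40, -90))
  expect_error(sim_config(list(), 2015, "spring"), "non-empty")
  expect_error(sim_config(st, 2015, "spring", weather_ar1_rho = 1),
               "weather_ar1_rho")
  expect_error(sim_config(st, 2015, "spring", dropout_rate = 1),
               "dropout_rate")
  expect_error(station_config("K", 60, -90), "latitude")
  expect_error(station_config("K", 40, -90, night_length = 20),
               "night_length")
  expect_error(
    sim_config(list(station_config("KAAA", 40, -90),
                    station_config("KAAA", 41, -91)), 2015, "spring"),
    "duplicate")
})

test_that("missing weather for a night raises a generation error naming it", {
  cfg <- one_station_cfg(seed = 7)
  w <- simulate_weather(cfg)
  cut <- as.Date("2015-04-15")
  w_missing <- w[night_of_timestamp(timestamp_utc, -90) != cut]
  expect_error(simulate_migration(cfg, w_missing), "2015-04-15")
})

test_that("dropout removes whole nights at the configured rate", {
  retained <- vapply(1:10, function(i) {
    cfg <- one_station_cfg(dropout_rate = 0.1, seed = 100 + i)
    mig <- simulate_migration(cfg, simulate_weather(cfg))
    uniqueN(mig$profiles$night_id)
  }, numeric(1))
  # binomial expectation 102 * 0.9 = 91.8
  expect_gte(mean(retained), 88)
  expect_lte(mean(retained), 95)
})

test_that("generate_dataset writes a reproducible manifest round trip", {
  cfg <- sim_config(
    list(station_config("KAAA", 40, -90, night_length = 8),
         station_config("KBBB", 35, -80, night_length = 8)),
    years = 2014:2016, season = "spring", seed = 8)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  man1 <- generate_dataset(cfg, d1)
  ds <- load_dataset(d1)
  man2 <- generate_dataset(ds$config, d2) # regenerate from manifest config
  expect_identical(man1$files$profiles$md5, man2$files$profiles$md5)
  expect_identical(man1$files$weather$md5, man2$files$weather$md5)
  expect_identical(man1$files$truth$md5, man2$files$truth$md5)
  # 2 stations x 3 years = 6 station-year groups
  ds$profiles[, year := format(night_id, "%Y")]
  expect_equal(nrow(unique(ds$profiles[, .(station_id, year)])), 6L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("expected top-10% share never decreases with pulse_sigma", {
  share_at <- function(sigma, seed) {
    cfg <- one_station_cfg(pulse_sigma = sigma, dropout_rate = 0,
                           seed = seed)
    mig <- simulate_migration(cfg, simulate_weather(cfg))
    s <- build_season(integrate_profiles(mig$profiles), "spring", 2015)
    concentration_curve(s, 0.10)$share
  }
  seeds <- 200 + 1:6
  means <- vapply(c(0.3, 1.1, 2.0), function(sg)
    mean(vapply(seeds, function(sd) share_at(sg, sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) > -0.02)) # non-decreasing within MC noise
})
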