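# Night/time conventions -------------------------------------------------
#
# A "night" is labeled by the local calendar date of sunset; all samples of
# that night (including post-midnight ones) carry that night_id. Local time
# is idealized solar time (UTC + longitude/15 hours); sunset is fixed at
# 19:00 local solar. Weather is generated on a 3-h grid of 8 timestamps per
# night anchored at 12:00 local solar of the sunset date, so every radar
# sample has a weather record within 1.5 h.

lon_offset_sec <- function(longitude) round(longitude / 15 * 3600)

night_start_utc <- function(night_id, longitude) {
  # 12:00 local solar of the sunset date, in UTC
  as.POSIXct(as.character(night_id), tz = "UTC") +
    12 * 3600 - lon_offset_sec(longitude)
}

sunset_utc <- function(night_id, longitude) {
  night_start_utc(night_id, longitude) + 7 * 3600 # 19:00 local solar
}

#' Map a weather timestamp to its night
#'
#' Timestamps from 12:00 local solar of date `d` up to (but excluding)
#' 12:00 of `d + 1` belong to night `d`.
#'
#' @param timestamp_utc POSIXct (UTC).
#' @param longitude Station longitude, degrees east.
#' @return `Date` vector of night ids.
#' @export
night_of_timestamp <- function(timestamp_utc, longitude) {
  as.Date(timestamp_utc + lon_offset_sec(longitude) - 12 * 3600, tz = "UTC")
}

# stationary AR(1) with N(0,1) marginals
ar1_series <- function(n, rho) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  if (n > 1) {
    innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  }
  x
}

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stage) %% 2147483399) + 1L
}

#' Simulate reanalysis-like weather covariates
#'
#' Generates one record per station x 3-h timestamp x 100-m height level
#' (0-3000 m) over the configured seasons. Winds follow a nightly AR(1)
#' synoptic driver with coefficient `weather_ar1_rho`, plus height-dependent
#' shear and within-night noise; bounded fields (relative humidity, cloud
#' cover, visibility) are clipped into their physical ranges. Output is a
#' pure function of (config, seed).
#'
#' @param config A [sim_config()].
#' @return A `data.table` with columns `station_id`, `timestamp_utc`
#'   (POSIXct UTC), `height_m`, `uwind_ms`, `vwind_ms`, `temp_c`, `sp_pa`,
#'   `rh_pct`, `tcc_pct`, `vis_m`, `mslp_pa`.
#' @export
#' @examples
#' cfg <- sim_config(list(station_config("KAAA", 40, -90)),
#'                   years = 2015, season = "spring", seed = 1)
#' wx <- simulate_weather(cfg)
#' nrow(wx) # 102 nights x 8 timestamps x 31 levels
simulate_weather <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: 'config' must be a sim_config")
  set.seed(derive_seed(config$seed, 1L))
  heights <- weather_heights()
  nh <- length(heights)
  out <- vector("list", length(config$stations) * length(config$years))
  k <- 0L
  for (st in config$stations) {
    for (yr in sort(config$years)) {
      nights <- season_nights(config$season, yr)
      nd <- length(nights)
      ord <- as.integer(format(nights, "%j"))
      # nightly synoptic drivers, one AR(1) per field family
      z_v <- ar1_series(nd, config$weather_ar1_rho)
      z_u <- ar1_series(nd, config$weather_ar1_rho)
      z_t <- ar1_series(nd, config$weather_ar1_rho)
      z_p <- ar1_series(nd, config$weather_ar1_rho)
      z_r <- ar1_series(nd, config$weather_ar1_rho)
      z_c <- ar1_series(nd, config$weather_ar1_rho)

      # 8 timestamps per night, anchored at 12:00 local solar of sunset date
      ts0 <- night_start_utc(nights, st$longitude)
      nt <- 8L
      # per (night, timestamp) surface-scale fields, replicated over height
      d_idx_ts <- rep(seq_len(nd), each = nt)
      sp_ts <- 101325 + 500 * z_p[d_idx_ts] + rnorm(nd * nt, sd = 100)
      mslp_ts <- 101325 + 550 * z_p[d_idx_ts] + rnorm(nd * nt, sd = 100)
      rh_ts <- pmin(pmax(60 + 18 * z_r[d_idx_ts] + rnorm(nd * nt, sd = 5),
                         0), 100)
      tcc_ts <- pmin(pmax(45 + 35 * z_c[d_idx_ts] + rnorm(nd * nt, sd = 10),
                          0), 100)
      vis_ts <- pmax(18000 - 9000 * z_c[d_idx_ts] + rnorm(nd * nt, sd = 2000),
                     0)

      n_rec <- nd * nt * nh
      d_idx <- rep(seq_len(nd), each = nt * nh)
      t_idx <- rep(rep(seq_len(nt), each = nh), times = nd)
      h <- rep(heights, times = nd * nt)
      ts_idx <- (d_idx - 1L) * nt + t_idx

      # seasonal surface temperature trend, -6.5 C/km lapse rate
      t_seas <- if (config$season == "spring") {
        5 + 0.15 * (ord[d_idx] - 60)
      } else {
        25 - 0.15 * (ord[d_idx] - 213)
      }

      tab <- data.table(
        station_id = st$station_id,
        timestamp_utc = ts0[d_idx] + (t_idx - 1L) * 3L * 3600,
        height_m = h,
        uwind_ms = 3 + 2.5 * z_u[d_idx] + 2 * h / 1000 +
          rnorm(n_rec, sd = 0.8),
        vwind_ms = 4 * z_v[d_idx] + 1.5 * h / 1000 +
          rnorm(n_rec, sd = 0.8),
        temp_c = t_seas - 6.5 * h / 1000 + 3 * z_t[d_idx] +
          rnorm(n_rec, sd = 0.5),
        sp_pa = sp_ts[ts_idx],
        rh_pct = rh_ts[ts_idx],
        tcc_pct = tcc_ts[ts_idx],
        vis_m = vis_ts[ts_idx],
        mslp_pa = mslp_ts[ts_idx]
      )
      k <- k + 1L
      out[[k]] <- tab
    }
  }
  rbindlist(out)
}

#' Perturb weather into a forecast channel
#'
#' Returns a copy of a reanalysis-like weather table with independent
#' Gaussian error of SD `error_sd` (m/s) added to both wind components,
#' standing in for forecast-versus-reanalysis differences. `error_sd = 0`
#' returns the table unchanged (the idealized limit).
#'
#' @param weather Weather table from [simulate_weather()].
#' @param error_sd Non-negative SD in m/s.
#' @param seed Integer seed for the error draw.
#' @return A `data.table` with the same columns.
#' @export
perturb_forecast_weather <- function(weather, error_sd, seed = 1L) {
  stopifnot(is.numeric(error_sd), length(error_sd) == 1L, error_sd >= 0)
  fw <- copy(as.data.table(weather))
  if (error_sd > 0) {
    set.seed(derive_seed(seed, 2L))
    fw[, uwind_ms := uwind_ms + rnorm(.N, sd = error_sd)]
    fw[, vwind_ms := vwind_ms + rnorm(.N, sd = error_sd)]
  }
  fw[]
}
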