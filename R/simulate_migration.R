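# Within-night activity shape: unimodal, zero at sunset and sunrise, peak
# at 40% of the night. Weights are normalized so that the trapezoid rule on
# the 30-min grid integrates to exactly 1 over the night, which makes the
# noise-free nightly integral recover the latent intensity exactly.
night_shape <- function(night_length) {
  minutes <- seq(0L, as.integer(night_length * 60), by = 30L)
  x <- minutes / (night_length * 60)
  s <- x^1.8 * (1 - x)^2.7
  h <- 0.5 # hours between samples
  tw <- c(h / 2, rep(h, length(s) - 2L), h / 2)
  list(minutes = minutes, w = s / sum(s * tw))
}

# exponential decay of activity with altitude; shares over the 30 bins sum to 1
height_shares <- function(altitude_scale) {
  mids <- profile_bins() + 50
  q <- exp(-mids / altitude_scale)
  q / sum(q)
}

# nightly mean tailwind (m/s) along the seasonal heading, from weather
# records below 1000 m assigned to each night
nightly_tailwind <- function(weather, longitude, season) {
  w <- as.data.table(weather)[height_m <= 1000]
  w[, night_id := night_of_timestamp(timestamp_utc, longitude)]
  sgn <- tailwind_sign(season)
  w[, .(tailwind_ms = sgn * mean(vwind_ms)), keyby = night_id]
}

#' Simulate radar-like migration profiles
#'
#' Generates 30-min, altitude-binned reflectivity profiles whose nightly
#' totals follow a Gaussian seasonal envelope modulated by weather-driven
#' pulses: latent nightly intensity =
#' `envelope(ordinal date) * exp(pulse_beta * favorability + pulse_sigma * noise)`,
#' where favorability is the standardized nightly mean tailwind along the
#' seasonal migration heading (north in spring, south in autumn). Within a
#' night, activity rises after sunset, peaks in the first half of the night
#' and declines to sunrise; across altitude it decays exponentially with
#' scale `altitude_scale`. Observed reflectivity is the latent rate divided
#' by simulated groundspeed times log-normal observation noise; whole nights
#' drop out independently with probability `dropout_rate`.
#'
#' @param config A [sim_config()].
#' @param weather Weather table from [simulate_weather()] covering every
#'   station-night of the config.
#' @return A list with elements
#'   \describe{
#'     \item{profiles}{`data.table`: `station_id`, `latitude`, `longitude`,
#'       `night_id`, `minutes_after_sunset`, `height_bin_m`,
#'       `eta_cm2_per_km3`, `groundspeed_kmh`, `direction_deg`.}
#'     \item{truth}{`data.table` of noise-free ground truth per station-night:
#'       `station_id`, `night_id`, `latent_total` (column-integrated passage,
#'       cm^2/km/night; divide by the radar cross-section for birds/km/night)
#'       and `favorability` (standardized tailwind). Truth covers all nights,
#'       including dropped-out ones.}
#'   }
#' @export
simulate_migration <- function(config, weather) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: 'config' must be a sim_config")
  weather <- as.data.table(weather)
  set.seed(derive_seed(config$seed, 3L))
  q <- height_shares(config$altitude_scale)
  bins <- profile_bins()
  nb <- length(bins)
  bin_height_km <- 0.1
  heading <- if (config$season == "spring") 0 else 180

  prof_out <- list(); truth_out <- list(); k <- 0L
  for (st in config$stations) {
    wx_st <- weather[station_id == st$station_id]
    shape <- night_shape(st$night_length)
    nt <- length(shape$minutes)
    for (yr in sort(config$years)) {
      nights <- season_nights(config$season, yr)
      nd <- length(nights)
      ord <- as.integer(format(nights, "%j"))

      tw <- nightly_tailwind(
        wx_st[night_of_timestamp(timestamp_utc, st$longitude) %in% nights],
        st$longitude, config$season
      )
      missing <- setdiff(as.character(nights), as.character(tw$night_id))
      if (length(missing) > 0L)
        stop("generation error: no weather for station ", st$station_id,
             " night ", missing[1])
      tw <- tw[match(nights, night_id)]

      s <- sd(tw$tailwind_ms)
      fav <- if (is.na(s) || s == 0) rep(0, nd) else
        (tw$tailwind_ms - mean(tw$tailwind_ms)) / s

      # inter-annual phenology: the peak date shifts per station-year
      mu_y <- config$phenology_peak_mu +
        if (config$phenology_jitter_sd > 0)
          rnorm(1, sd = config$phenology_jitter_sd) else 0
      env <- if (config$phenology_sd > 0) {
        config$envelope_amplitude *
          exp(-(ord - mu_y)^2 / (2 * config$phenology_sd^2))
      } else {
        config$envelope_amplitude * as.numeric(ord == round(mu_y))
      }
      pulse <- exp(config$pulse_beta * fav +
                     config$pulse_sigma * rnorm(nd))
      intensity <- env * pulse # cm^2/km/night, column-integrated

      gs <- pmax(12 * 3.6 + 3.6 * tw$tailwind_ms, 1) # km/h, per night

      n_rec <- nd * nt * nb
      d_idx <- rep(seq_len(nd), each = nt * nb)
      t_idx <- rep(rep(seq_len(nt), each = nb), times = nd)
      b_idx <- rep(seq_len(nb), times = nd * nt)

      latent_rate <- intensity[d_idx] * shape$w[t_idx] * q[b_idx] /
        bin_height_km # cm^2/km^2/h
      noise <- if (config$obs_sigma > 0) {
        exp(rnorm(n_rec, mean = -config$obs_sigma^2 / 2,
                  sd = config$obs_sigma))
      } else rep(1, n_rec)
      eta <- latent_rate * noise / gs[d_idx]
      dir <- (heading + rnorm(n_rec, sd = 10)) %% 360

      keep_night <- if (config$dropout_rate > 0) {
        rbinom(nd, 1L, 1 - config$dropout_rate) == 1L
      } else rep(TRUE, nd)

      prof <- data.table(
        station_id = st$station_id,
        latitude = st$latitude,
        longitude = st$longitude,
        night_id = nights[d_idx],
        minutes_after_sunset = shape$minutes[t_idx],
        height_bin_m = bins[b_idx],
        eta_cm2_per_km3 = eta,
        groundspeed_kmh = gs[d_idx],
        direction_deg = dir
      )[keep_night[d_idx]]

      k <- k + 1L
      prof_out[[k]] <- prof
      truth_out[[k]] <- data.table(
        station_id = st$station_id, night_id = nights,
        latent_total = intensity, favorability = fav
      )
    }
  }
  list(profiles = rbindlist(prof_out), truth = rbindlist(truth_out))
}
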