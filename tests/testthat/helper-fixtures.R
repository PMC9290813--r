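library(data.table)

# one-station season series from a plain traffic vector; nights are
# consecutive dates from the season start (plus start_offset nights)
make_season <- function(traffic, season = "spring", year = 2015,
                        station = "KTST", start_offset = 0L,
                        min_nights = 1L) {
  b <- season_bounds(season, year)
  nights <- data.table(
    station_id = station,
    night_id = b[["start"]] + start_offset + seq_along(traffic) - 1L,
    traffic = as.numeric(traffic),
    n_samples = 21L, complete = TRUE
  )
  build_season(nights, season, year, min_nights = min_nights)
}

# nightly predictions table aligned with a season made by make_season
make_predictions <- function(predicted, season = "spring", year = 2015,
                             station = "KTST", start_offset = 0L) {
  b <- season_bounds(season, year)
  data.table(
    station_id = station,
    night_id = b[["start"]] + start_offset + seq_along(predicted) - 1L,
    predicted_traffic = as.numeric(predicted)
  )
}

# profile table with constant reflectivity/speed on a full 30-min x 30-bin
# grid; night_hours sets the sunset-to-sunrise span
make_constant_profiles <- function(eta = 11, speed = 50, night_hours = 10,
                                   station = "KTST",
                                   night = as.Date("2015-04-01")) {
  minutes <- seq(0L, as.integer(night_hours * 60), by = 30L)
  bins <- seq(0L, 2900L, by = 100L)
  CJ(minutes_after_sunset = minutes, height_bin_m = bins)[, `:=`(
    station_id = station, night_id = night,
    eta_cm2_per_km3 = eta, groundspeed_kmh = speed,
    direction_deg = 0
  )][]
}

# exhaustive minimal-subset oracle: smallest number of nights whose traffic
# sums to at least target * total, over all 2^n subsets
oracle_min_nights <- function(traffic, target) {
  n <- length(traffic)
  stopifnot(n <= 16L)
  masks <- seq_len(2^n - 1L)
  bits <- vapply(seq_len(n), function(b) bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0L,
                 logical(length(masks)))
  sums <- as.vector(bits %*% traffic)
  sizes <- rowSums(bits)
  min(sizes[sums >= target * sum(traffic) - 1e-9])
}

# independent brute-force fixed-window search: explicit loops over every
# width and start, per-year shares summed with sum(), mean across years
oracle_fixed_window <- function(v, target, max_width = 100L) {
  # v: years x positions matrix of nightly traffic
  S <- ncol(v)
  totals <- rowSums(v)
  for (w in seq_len(min(max_width, S))) {
    best_start <- NA_integer_; best_cap <- -Inf
    for (s in seq_len(S - w + 1L)) {
      caps <- numeric(nrow(v))
      for (y in seq_len(nrow(v)))
        caps[y] <- sum(v[y, s:(s + w - 1L)]) / totals[y]
      m <- mean(caps)
      if (m > best_cap + 1e-12) { best_cap <- m; best_start <- s }
    }
    if (best_cap >= target - 1e-12)
      return(list(width = w, start = best_start, mean_capture = best_cap))
  }
  list(width = NA_integer_, start = NA_integer_, mean_capture = NA_real_)
}

# small synthetic nightly traffic vector following the generator's nightly
# law (Gaussian envelope x log-normal pulse), without the profile layer
pulsed_traffic <- function(n = 102L, mu = 51, sd = 16, beta = 0.8,
                           sigma = 1.1) {
  env <- exp(-((seq_len(n) - mu)^2) / (2 * sd^2))
  env * exp(beta * rnorm(n) + sigma * rnorm(n))
}

default_probe_stations <- function() {
  list(
    station_config("KNOR", 45, -93, night_length = 10),
    station_config("KMID", 39, -84, night_length = 10),
    station_config("KSOU", 33, -90, night_length = 10)
  )
}
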