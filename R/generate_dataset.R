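sim_config_to_list <- function(config) {
  list(
    stations = lapply(config$stations, function(s) s[c(
      "station_id", "latitude", "longitude", "night_length")]),
    years = config$years, season = config$season,
    phenology_peak_mu = config$phenology_peak_mu,
    phenology_sd = config$phenology_sd,
    phenology_jitter_sd = config$phenology_jitter_sd,
    envelope_amplitude = config$envelope_amplitude,
    pulse_beta = config$pulse_beta, pulse_sigma = config$pulse_sigma,
    weather_ar1_rho = config$weather_ar1_rho, obs_sigma = config$obs_sigma,
    forecast_error_sd = config$forecast_error_sd,
    dropout_rate = config$dropout_rate,
    altitude_scale = config$altitude_scale, seed = config$seed
  )
}

sim_config_from_list <- function(x) {
  stations <- lapply(x$stations, function(s)
    station_config(s$station_id, s$latitude, s$longitude, s$night_length))
  sim_config(
    stations = stations, years = unlist(x$years), season = x$season,
    phenology_peak_mu = x$phenology_peak_mu, phenology_sd = x$phenology_sd,
    phenology_jitter_sd = x$phenology_jitter_sd,
    envelope_amplitude = x$envelope_amplitude, pulse_beta = x$pulse_beta,
    pulse_sigma = x$pulse_sigma, weather_ar1_rho = x$weather_ar1_rho,
    obs_sigma = x$obs_sigma, forecast_error_sd = x$forecast_error_sd,
    dropout_rate = x$dropout_rate, altitude_scale = x$altitude_scale,
    seed = x$seed
  )
}

#' Generate and write a synthetic dataset
#'
#' Runs [simulate_weather()] and [simulate_migration()] and writes three
#' delimited tables (`profiles.csv`, `weather.csv`, `truth.csv`) plus a JSON
#' manifest recording the full configuration and seed. Re-running with the
#' same config reproduces byte-identical tables.
#'
#' @param config A [sim_config()].
#' @param output_dir Writable directory (created if absent).
#' @return Invisibly, the manifest as a list (`config`, `files`, with file
#'   MD5 checksums).
#' @export
generate_dataset <- function(config, output_dir) {
  if (!inherits(config, "sim_config"))
    stop("configuration error: 'config' must be a sim_config")
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!ok || file.access(output_dir, 2L) != 0L)
    stop("I/O error: cannot write to ", output_dir)

  weather <- simulate_weather(config)
  mig <- simulate_migration(config, weather)

  paths <- file.path(output_dir, c("profiles.csv", "weather.csv", "truth.csv"))
  names(paths) <- c("profiles", "weather", "truth")
  fwrite(mig$profiles, paths[["profiles"]], dateTimeAs = "ISO")
  fwrite(weather, paths[["weather"]], dateTimeAs = "ISO")
  fwrite(mig$truth, paths[["truth"]], dateTimeAs = "ISO")

  manifest <- list(
    config = sim_config_to_list(config),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory containing the three tables and manifest.
#' @return List with `profiles`, `weather`, `truth` (`data.table`s, dates
#'   and timestamps parsed) and `config` (the reconstructed [sim_config()]).
#' @export
load_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("I/O error: no manifest at ", man_path)
  man <- jsonlite::read_json(man_path)
  profiles <- fread(file.path(dir, "profiles.csv"))
  profiles[, night_id := as.Date(night_id)]
  weather <- fread(file.path(dir, "weather.csv"))
  weather[, timestamp_utc := as.POSIXct(timestamp_utc, tz = "UTC")]
  truth <- fread(file.path(dir, "truth.csv"))
  truth[, night_id := as.Date(night_id)]
  list(profiles = profiles, weather = weather, truth = truth,
       config = sim_config_from_list(man$config))
}
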