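hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' Collects the simulation settings, model settings, target fractions and
#' exploration grid of a full pipeline run. Accepts a nested list or the
#' path of a YAML file with the same structure.
#'
#' @param config A list (or YAML path) with elements `simulation` (the
#'   arguments of [sim_config()] with stations as lists), and optionally
#'   `model` (`n_rounds`, `max_train_rows`), `targets`, `grid`,
#'   `cross_section`, `bin_height`, `min_nights`, `seed`.
#' @return A `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$simulation))
  defaults <- list(
    model = list(n_rounds = 1000L, max_train_rows = Inf),
    targets = c(0.25, 0.5, 0.75),
    grid = seq(0.05, 0.95, by = 0.05),
    cross_section = 11, bin_height = 0.1, min_nights = 100L,
    seed = 1L
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$model$n_rounds)) config$model$n_rounds <- 1000L
  if (is.null(config$model$max_train_rows))
    config$model$max_train_rows <- Inf
  config$seed <- as.integer(config$seed)
  config$simulation$seed <- config$seed
  structure(config, class = "pipeline_config")
}

write_stage_manifest <- function(dir, stage, cfg_hash, seed, outputs) {
  manifest <- list(
    stage = stage, config_hash = cfg_hash, seed = seed,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest,
                       file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

stage_current <- function(dir, stage, cfg_hash, outputs) {
  mp <- file.path(dir, paste0(stage, "_manifest.json"))
  if (!file.exists(mp) || !all(file.exists(outputs))) return(FALSE)
  man <- tryCatch(jsonlite::read_json(mp), error = function(e) NULL)
  !is.null(man) && identical(man$config_hash, cfg_hash)
}

#' Run the full pipeline
#'
#' Executes simulate -> integrate -> leave-one-year-out train/predict ->
#' select (all three methods) -> evaluate. Every stage writes its outputs
#' plus a manifest recording the stage name, a hash of the configuration,
#' the seed, and output checksums, so each file is traceable to (config,
#' seed). With `resume = TRUE`, stages whose outputs already exist under
#' the same config hash are skipped.
#'
#' @param config A [pipeline_config()] (or list / YAML path accepted by
#'   it).
#' @param output_dir Output directory.
#' @param resume Skip up-to-date stages. Default `FALSE`.
#' @param quiet Suppress progress messages. Default `FALSE`.
#' @return Invisibly, the run manifest: per-stage manifests plus key output
#'   paths.
#' @export
run_pipeline <- function(config, output_dir, resume = FALSE, quiet = FALSE) {
  config <- pipeline_config(unclass(config))
  cfg_hash <- hash_object(unclass(config))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stages <- list()

  scfg <- do.call(sim_config, c(
    list(stations = lapply(config$simulation$stations, function(s)
      do.call(station_config, s))),
    config$simulation[setdiff(names(config$simulation), "stations")]
  ))

  # -- simulate ------------------------------------------------------------
  ds_dir <- file.path(output_dir, "dataset")
  sim_outputs <- file.path(ds_dir, c("profiles.csv", "weather.csv",
                                     "truth.csv"))
  if (resume && stage_current(output_dir, "simulate", cfg_hash, sim_outputs)) {
    say("simulate: up to date, skipped")
  } else {
    say("simulate: generating dataset (", length(scfg$stations),
        " stations x ", length(scfg$years), " years, ", scfg$season, ")")
    tryCatch(generate_dataset(scfg, ds_dir),
             error = function(e) stop("stage simulate failed: ",
                                      conditionMessage(e)))
    stages$simulate <- write_stage_manifest(output_dir, "simulate", cfg_hash,
                                            config$seed, sim_outputs)
  }
  ds <- load_dataset(ds_dir)

  # -- integrate -----------------------------------------------------------
  nightly_path <- file.path(output_dir, "nightly.csv")
  if (resume && stage_current(output_dir, "integrate", cfg_hash,
                              nightly_path)) {
    say("integrate: up to date, skipped")
    nightly <- fread(nightly_path)
    nightly[, night_id := as.Date(night_id)]
  } else {
    nightly <- tryCatch(
      integrate_profiles(ds$profiles, config$cross_section,
                         config$bin_height),
      error = function(e) stop("stage integrate failed: ",
                               conditionMessage(e)))
    fwrite(nightly, nightly_path, dateTimeAs = "ISO")
    say("integrate: ", nrow(nightly), " station-nights (",
        sum(!nightly$complete), " incomplete)")
    stages$integrate <- write_stage_manifest(output_dir, "integrate",
                                             cfg_hash, config$seed,
                                             nightly_path)
  }
  seasons <- build_seasons(nightly, scfg$season, config$min_nights)
  n_valid <- sum(vapply(seasons, `[[`, logical(1), "valid"))
  say("integrate: ", n_valid, "/", length(seasons),
      " station-seasons pass the >=", config$min_nights, "-night filter")

  # -- forecast (LOYO) -----------------------------------------------------
  pred_path <- file.path(output_dir, "predictions.csv")
  skill_path <- file.path(output_dir, "skill.csv")
  if (resume && stage_current(output_dir, "forecast", cfg_hash,
                              c(pred_path, skill_path))) {
    say("forecast: up to date, skipped")
    predictions <- fread(pred_path)
    predictions[, night_id := as.Date(night_id)]
  } else {
    feats <- tryCatch(
      build_features(ds$profiles, ds$weather, scfg$stations),
      error = function(e) stop("stage forecast failed: ",
                               conditionMessage(e)))
    fweather <- perturb_forecast_weather(ds$weather,
                                         scfg$forecast_error_sd,
                                         seed = config$seed)
    ffeats <- if (scfg$forecast_error_sd > 0)
      build_features(ds$profiles, fweather, scfg$stations) else NULL
    say("forecast: training ", length(unique(features_year(feats))),
        " leave-one-year-out folds on ", nrow(feats), " rows")
    loyo <- tryCatch(
      loyo_evaluate(feats, ffeats, nightly = nightly,
                    season = scfg$season,
                    n_rounds = config$model$n_rounds,
                    max_train_rows = config$model$max_train_rows,
                    seed = config$seed),
      error = function(e) stop("stage forecast failed: ",
                               conditionMessage(e)))
    predictions <- loyo$predictions
    fwrite(predictions, pred_path, dateTimeAs = "ISO")
    fwrite(loyo$per_year, skill_path)
    say("forecast: mean held-out variance explained ",
        sprintf("%.3f", loyo$mean_r2))
    stages$forecast <- write_stage_manifest(output_dir, "forecast",
                                            cfg_hash, config$seed,
                                            c(pred_path, skill_path))
  }

  # -- select --------------------------------------------------------------
  results_path <- file.path(output_dir, "results.csv")
  if (resume && stage_current(output_dir, "select", cfg_hash,
                              results_path)) {
    say("select: up to date, skipped")
    results_tab <- fread(results_path)
  } else {
    results <- tryCatch(
      select_all_methods(seasons, predictions, targets = config$targets),
      error = function(e) stop("stage select failed: ",
                               conditionMessage(e)))
    results_tab <- selection_table(results)
    fwrite(results_tab, results_path)
    say("select: ", nrow(results_tab), " selection results written")
    stages$select <- write_stage_manifest(output_dir, "select", cfg_hash,
                                          config$seed, results_path)
  }

  # -- evaluate ------------------------------------------------------------
  conc_path <- file.path(output_dir, "concentration.csv")
  curve_path <- file.path(output_dir, "capture_curve.csv")
  if (resume && stage_current(output_dir, "evaluate", cfg_hash,
                              c(conc_path, curve_path))) {
    say("evaluate: up to date, skipped")
  } else {
    valid_seasons <- Filter(function(s) s$valid, seasons)
    conc <- rbindlist(lapply(valid_seasons, concentration_curve,
                             fractions = config$grid))
    fwrite(conc, conc_path)
    fwrite(capture_curve(results_tab), curve_path)
    say("evaluate: concentration and capture curves written")
    stages$evaluate <- write_stage_manifest(output_dir, "evaluate",
                                            cfg_hash, config$seed,
                                            c(conc_path, curve_path))
  }

  invisible(list(config_hash = cfg_hash, seed = config$seed,
                 stages = stages,
                 paths = list(dataset = ds_dir, nightly = nightly_path,
                              predictions = pred_path, skill = skill_path,
                              results = results_path,
                              concentration = conc_path,
                              capture_curve = curve_path)))
}
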