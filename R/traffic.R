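#' Per-sample migration rate
#'
#' The migration rate of one profile sample is reflectivity times
#' groundspeed: cm^2/km^3 x km/h = cm^2/km^2/h.
#'
#' @param eta Reflectivity, cm^2/km^3 (non-negative).
#' @param groundspeed Groundspeed, km/h (non-negative).
#' @return Rate in cm^2/km^2/h.
#' @export
#' @examples
#' bin_rate(11, 50) # 550
bin_rate <- function(eta, groundspeed) {
  if (any(!is.finite(eta)) || any(!is.finite(groundspeed)))
    stop("validation error: eta and groundspeed must be finite")
  if (any(eta < 0) || any(groundspeed < 0))
    stop("validation error: eta and groundspeed must be non-negative")
  eta * groundspeed
}

# Trapezoidal integration of the rate-vs-time curve, vectorized over
# (station, night, height bin) groups. Returns the per-night traffic table.
# gap_fill = "interpolate" spans interior missing time steps with a single
# trapezoid between the flanking samples; "drop" integrates only segments
# between samples exactly 30 min apart.
integrate_core <- function(profiles, cross_section, bin_height, gap_fill) {
  p <- as.data.table(profiles)
  req <- c("station_id", "night_id", "minutes_after_sunset", "height_bin_m",
           "eta_cm2_per_km3", "groundspeed_kmh")
  miss <- setdiff(req, names(p))
  if (length(miss) > 0L)
    stop("validation error: profiles table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(p, by = c("station_id", "night_id",
                              "minutes_after_sunset", "height_bin_m")))
    stop("validation error: duplicate (station, night, time, bin) samples")
  p <- p[order(station_id, night_id, height_bin_m, minutes_after_sunset)]
  p[, rate := bin_rate(eta_cm2_per_km3, groundspeed_kmh)]

  # trapezoid segments within each (station, night, bin) run
  p[, `:=`(
    dt_h = (shift(minutes_after_sunset, type = "lead") -
              minutes_after_sunset) / 60,
    rate_next = shift(rate, type = "lead")
  ), by = .(station_id, night_id, height_bin_m)]
  seg <- p[!is.na(dt_h)]
  if (nrow(seg) > 0 && any(seg$dt_h <= 0))
    stop("validation error: unsorted or duplicate timestamps within a bin")
  if (gap_fill == "drop") seg <- seg[abs(dt_h - 0.5) < 1e-9]
  auc <- seg[, .(auc = sum(dt_h * (rate + rate_next) / 2)),
             by = .(station_id, night_id)]

  nightly <- p[, .(
    n_samples = uniqueN(minutes_after_sunset),
    span_min = max(minutes_after_sunset) - min(minutes_after_sunset)
  ), by = .(station_id, night_id)]
  nightly <- auc[nightly, on = c("station_id", "night_id")]
  nightly[is.na(auc) & n_samples >= 2L, auc := 0]
  nightly[, traffic := auc * bin_height / cross_section]
  nightly[n_samples < 2L, traffic := NA_real_]
  # a night missing more than 25% of its expected 30-min steps is incomplete
  nightly[, expected := span_min / 30 + 1]
  nightly[, complete := n_samples >= 2L &
            (expected - n_samples) / expected <= 0.25]
  nightly[, c("auc", "span_min", "expected") := NULL]
  setorder(nightly, station_id, night_id)
  nightly[]
}

#' Integrate one station-night of profiles into nightly traffic
#'
#' Per height bin, the rate-versus-time curve (reflectivity x groundspeed,
#' cm^2/km^2/h) is integrated over the night by the trapezoid rule (time in
#' hours), giving cm^2/km^2/night; multiplying by the bin height (km) gives
#' cm^2/km/night; summing over bins and dividing by the radar cross-section
#' of one bird (cm^2) yields the nightly traffic rate in birds/km/night.
#' Time steps present in some bins but missing in others are treated as
#' missing for those bins only.
#'
#' @param samples Profile samples for a single station-night (columns as in
#'   the profiles table of [simulate_migration()]).
#' @param cross_section Radar cross-section of an average migrant, cm^2.
#'   Default 11.
#' @param bin_height Altitude bin height, km. Default 0.1.
#' @param gap_fill `"interpolate"` (default) spans interior missing time
#'   steps with a single trapezoid; `"drop"` integrates only adjacent 30-min
#'   pairs.
#' @return One-row `data.table`: `station_id`, `night_id`, `traffic`
#'   (birds/km/night; `NA` when fewer than 2 time steps), `n_samples`
#'   (distinct 30-min steps with data), `complete` (at least 2 steps and no
#'   more than 25% of expected steps missing).
#' @export
integrate_night <- function(samples, cross_section = 11, bin_height = 0.1,
                            gap_fill = c("interpolate", "drop")) {
  gap_fill <- match.arg(gap_fill)
  s <- as.data.table(samples)
  if (uniqueN(s, by = c("station_id", "night_id")) != 1L)
    stop("validation error: integrate_night expects a single station-night")
  integrate_core(s, cross_section, bin_height, gap_fill)
}

#' Integrate a whole profiles table into nightly traffic
#'
#' Vectorized over all station-nights; see [integrate_night()] for the
#' integration contract.
#'
#' @inheritParams integrate_night
#' @param profiles Profiles table (any number of station-nights).
#' @return `data.table` with one row per station-night.
#' @export
integrate_profiles <- function(profiles, cross_section = 11,
                               bin_height = 0.1,
                               gap_fill = c("interpolate", "drop")) {
  gap_fill <- match.arg(gap_fill)
  integrate_core(profiles, cross_section, bin_height, gap_fill)
}

#' Assemble a season series for one station
#'
#' Orders nights, applies the season-validity rule (a station-season-year is
#' valid only with at least `min_nights` complete nights) and totals the
#' seasonal passage over complete nights.
#'
#' @param nightly Nightly traffic table ([integrate_profiles()] rows) for
#'   one station and one season-year.
#' @param season `"spring"` or `"autumn"`.
#' @param year Calendar year.
#' @param min_nights Validity threshold on complete nights. Default 100.
#' @return A `season_series` list: `station_id`, `season`, `year`, `nights`
#'   (ordered `data.table`), `n_nights` (complete nights), `total_passage`
#'   (birds/km/season over complete nights), `valid`.
#' @export
build_season <- function(nightly, season, year, min_nights = 100L) {
  n <- as.data.table(nightly)
  season <- match.arg(season, c("spring", "autumn"))
  if (nrow(n) == 0L) {
    return(structure(
      list(station_id = NA_character_, season = season, year = year,
           nights = n, n_nights = 0L, total_passage = 0, valid = FALSE),
      class = "season_series"))
  }
  if (uniqueN(n$station_id) != 1L)
    stop("validation error: build_season expects a single station")
  b <- season_bounds(season, year)
  off <- n[night_id < b[["start"]] | night_id > b[["end"]]]
  if (nrow(off) > 0L)
    stop("validation error: night outside season bounds: ",
         as.character(off$night_id[1]))
  setorder(n, night_id)
  comp <- n[complete == TRUE]
  structure(
    list(station_id = n$station_id[1], season = season, year = year,
         nights = n, n_nights = nrow(comp),
         total_passage = sum(comp$traffic), valid = nrow(comp) >= min_nights),
    class = "season_series")
}

#' @export
print.season_series <- function(x, ...) {
  cat("<season_series> ", x$station_id, " ", x$season, " ", x$year, ": ",
      x$n_nights, " complete nights, total ",
      format(round(x$total_passage, 1), big.mark = ","),
      " birds/km/season, ", if (x$valid) "valid" else "invalid", "\n",
      sep = "")
  invisible(x)
}

#' Build all season series from a nightly table
#'
#' Splits a nightly traffic table by station and season-year and applies
#' [build_season()] to each.
#'
#' @param nightly Nightly traffic table for one season (possibly many
#'   stations and years).
#' @param season `"spring"` or `"autumn"`.
#' @param min_nights Validity threshold. Default 100.
#' @return Named list of `season_series` (`"<station>:<year>"`).
#' @export
build_seasons <- function(nightly, season, min_nights = 100L) {
  n <- as.data.table(nightly)
  n[, year := as.integer(format(night_id, "%Y"))]
  keys <- unique(n[, .(station_id, year)])
  setorder(keys, station_id, year)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    build_season(
      n[station_id == keys$station_id[i] & year == keys$year[i],
        !"year"],
      season, keys$year[i], min_nights
    )
  })
  names(out) <- paste0(keys$station_id, ":", keys$year)
  out
}
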