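# The 13 predictors, in contract order: three spatial, two temporal, eight
# atmospheric. Feature order is part of the model artifact contract.
feature_columns <- function() {
  c("latitude", "longitude", "height_m",
    "ordinal_date", "hour_after_sunset",
    "vwind_ms", "uwind_ms", "temp_c", "sp_pa", "rh_pct", "tcc_pct",
    "vis_m", "mslp_pa")
}

#' Build the model feature table
#'
#' Joins each 30-min profile sample to the weather record at the same
#' station and height level whose timestamp is nearest in time (ties broken
#' toward the earlier record), and computes the model response: the cube
#' root of reflectivity times groundspeed. Samples with no weather within
#' +/- `max_gap_h` hours are dropped with a message. Row order is
#' deterministic.
#'
#' @param profiles Profiles table (see [simulate_migration()]).
#' @param weather Weather table (see [simulate_weather()]).
#' @param stations List of [station_config()] (for the sunset clock).
#' @param max_gap_h Maximum tolerated radar-to-weather gap, hours. Default 3.
#' @return `data.table` with key columns (`station_id`, `night_id`,
#'   `minutes_after_sunset`, `height_bin_m`), the 13 predictors
#'   (`latitude`, `longitude`, `height_m`, `ordinal_date`,
#'   `hour_after_sunset`, `vwind_ms`, `uwind_ms`, `temp_c`, `sp_pa`,
#'   `rh_pct`, `tcc_pct`, `vis_m`, `mslp_pa`) and `response`
#'   (cm^(2/3)/km^(2/3)/h^(1/3)).
#' @export
build_features <- function(profiles, weather, stations, max_gap_h = 3) {
  p <- as.data.table(profiles)
  w <- as.data.table(weather)
  lon <- vapply(stations, `[[`, numeric(1), "longitude")
  names(lon) <- vapply(stations, `[[`, character(1), "station_id")
  miss_st <- setdiff(unique(p$station_id), names(lon))
  if (length(miss_st) > 0L)
    stop("validation error: no station_config for: ",
         paste(miss_st, collapse = ", "))

  ft <- p[, .(station_id, latitude, longitude, night_id,
              minutes_after_sunset, height_bin_m,
              eta_cm2_per_km3, groundspeed_kmh)]
  ft[, height_m := as.numeric(height_bin_m)]
  ft[, ts := sunset_utc(night_id, lon[station_id]) +
       minutes_after_sunset * 60]

  wx_cols <- c("uwind_ms", "vwind_ms", "temp_c", "sp_pa", "rh_pct",
               "tcc_pct", "vis_m", "mslp_pa")
  wx <- w[, c(list(station_id = station_id, height_m = as.numeric(height_m),
                   ts = timestamp_utc, wts = timestamp_utc),
              .SD), .SDcols = wx_cols]
  setkey(wx, station_id, height_m, ts)

  # earlier-or-equal and later-or-equal matches; pick the nearer, ties earlier
  prev <- wx[ft, on = .(station_id, height_m, ts), roll = +Inf]
  nxt <- wx[ft, on = .(station_id, height_m, ts), roll = -Inf]
  d_prev <- as.numeric(ft$ts) - as.numeric(prev$wts)
  d_next <- as.numeric(nxt$wts) - as.numeric(ft$ts)
  d_prev[is.na(d_prev)] <- Inf
  d_next[is.na(d_next)] <- Inf
  use_prev <- d_prev <= d_next
  out <- copy(prev)
  for (cl in wx_cols)
    set(out, which(!use_prev), cl, nxt[[cl]][!use_prev])
  gap <- pmin(d_prev, d_next)
  keep <- gap <= max_gap_h * 3600
  if (any(!keep))
    message("build_features: dropped ", sum(!keep),
            " sample(s) with no weather within ", max_gap_h, " h")
  out <- out[keep]

  out[, `:=`(
    ordinal_date = as.integer(format(night_id, "%j")),
    hour_after_sunset = minutes_after_sunset / 60,
    response = (eta_cm2_per_km3 * groundspeed_kmh)^(1 / 3)
  )]
  out <- out[, c(list(station_id = station_id, night_id = night_id,
                      minutes_after_sunset = minutes_after_sunset,
                      height_bin_m = height_bin_m),
                 .SD, list(response = response)),
             .SDcols = feature_columns()]
  setorder(out, station_id, night_id, minutes_after_sunset, height_bin_m)
  out[]
}
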