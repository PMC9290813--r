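new_selection_result <- function(method, series, action_nights,
                                 capture_fraction, target_fraction,
                                 detail = list()) {
  action_nights <- sort(action_nights)
  structure(
    list(method = method, station_id = series$station_id,
         season = series$season, year = series$year,
         action_nights = action_nights, n_nights = length(action_nights),
         capture_fraction = capture_fraction,
         target_fraction = target_fraction, detail = detail),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, " ", x$station_id, " ", x$season,
      " ", x$year, ": ", x$n_nights, " action night(s), capture ",
      sprintf("%.3f", x$capture_fraction), " (target ", x$target_fraction,
      ")\n", sep = "")
  invisible(x)
}

#' Flatten selection results into a table
#'
#' @param results List of selection results.
#' @return `data.table`: `method`, `station_id`, `season`, `year`,
#'   `target_fraction`, `n_nights`, `capture_fraction`,
#'   `threshold_or_window` (JSON-encoded detail).
#' @export
selection_table <- function(results) {
  rbindlist(lapply(results, function(r) data.table(
    method = r$method, station_id = r$station_id, season = r$season,
    year = r$year, target_fraction = r$target_fraction,
    n_nights = r$n_nights, capture_fraction = r$capture_fraction,
    threshold_or_window = as.character(
      jsonlite::toJSON(r$detail, auto_unbox = TRUE, digits = NA))
  )))
}

complete_nights <- function(series) {
  stopifnot(inherits(series, "season_series"))
  series$nights[complete == TRUE]
}

#' Idealized dynamic selection
#'
#' With perfect hindsight of realized passage, selects the minimum number of
#' action nights capturing at least `target_fraction` of the season's
#' measured passage: nights are ranked by measured traffic (descending, ties
#' broken by earlier date) and the smallest qualifying prefix is returned.
#' Top-k is provably minimal for this objective.
#'
#' @param series A `season_series` ([build_season()]).
#' @param target_fraction Target share of seasonal passage, in (0, 1\].
#' @return A `selection_result` with `method = "idealized_dynamic"`; its
#'   `detail` reports the continuous span (nights between first and last
#'   action night, inclusive) as a diagnostic.
#' @export
idealized_dynamic <- function(series, target_fraction) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  nights <- complete_nights(series)
  total <- sum(nights$traffic)
  if (!is.finite(total) || total <= 0)
    stop("selection undefined: total seasonal passage is zero")
  nights <- nights[order(-traffic, night_id)]
  k <- which(cumsum(nights$traffic) >= target_fraction * total - 1e-12)[1]
  sel <- nights[seq_len(k)]
  new_selection_result(
    "idealized_dynamic", series, sel$night_id,
    capture_fraction = sum(sel$traffic) / total,
    target_fraction = target_fraction,
    detail = list(span_nights = as.integer(
      max(sel$night_id) - min(sel$night_id)) + 1L)
  )
}

# match predicted nightly traffic to measured complete nights of one or
# more season series; returns (station_id, night_id, year, predicted,
# measured) for matched nights
match_pred_measured <- function(predicted, series_list) {
  pred <- as.data.table(predicted)
  stopifnot(all(c("station_id", "night_id", "predicted_traffic") %in%
                  names(pred)))
  meas <- rbindlist(lapply(series_list, function(s)
    complete_nights(s)[, .(station_id, night_id, measured = traffic,
                           year = s$year)]))
  pred[meas, on = c("station_id", "night_id"),
       .(station_id, night_id, year,
         predicted = predicted_traffic, measured)]
}

#' Derive an alert threshold from past years
#'
#' Scans the distinct predicted nightly intensities of the derivation years
#' and returns the largest threshold `t` such that nights with predicted
#' intensity at least `t` capture at least `target_fraction` of the total
#' measured passage (equivalently, the fewest action nights meeting the
#' target). Predictions gate selection; measured passage scores it, so the
#' threshold is robust to miscalibrated prediction magnitudes.
#'
#' @param predicted Nightly predictions (`station_id`, `night_id`,
#'   `predicted_traffic`) for the derivation years.
#' @param measured List of `season_series` for the same station and years.
#' @param target_fraction Target share, in (0, 1\].
#' @param pooling `"pooled"` (default) computes capture as summed captured
#'   passage over summed totals across derivation years; `"mean"` averages
#'   per-year capture shares.
#' @return A `threshold_policy` list: `target_fraction`, `threshold`,
#'   `derivation_years`, `pooling`.
#' @export
derive_threshold <- function(predicted, measured, target_fraction,
                             pooling = c("pooled", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (inherits(measured, "season_series")) measured <- list(measured)
  m <- match_pred_measured(predicted, measured)
  m <- m[!is.na(predicted)]
  if (nrow(m) == 0L)
    stop("validation error: no matched predicted/measured nights")
  setorder(m, -predicted, night_id)
  cand <- unique(m$predicted) # descending

  capture_at <- if (pooling == "pooled") {
    tot <- sum(m$measured)
    cum <- cumsum(m$measured) / tot
    # capture for threshold t = cumshare at the last row with predicted >= t
    idx <- findInterval(-cand, -m$predicted) # last row with predicted >= cand
    cum[idx]
  } else {
    totals <- m[, .(tot = sum(measured)), by = year]
    vapply(cand, function(t) {
      cap <- m[predicted >= t, .(capt = sum(measured)), by = year]
      cap <- merge(totals, cap, by = "year", all.x = TRUE)
      cap[is.na(capt), capt := 0]
      mean(cap$capt / cap$tot)
    }, numeric(1))
  }

  ok <- which(capture_at >= target_fraction - 1e-12)
  if (length(ok) == 0L) {
    warning("no threshold achieves the target; falling back to the ",
            "smallest candidate")
    thr <- cand[length(cand)]
  } else {
    thr <- cand[ok[1]] # largest qualifying threshold
  }
  years <- sort(unique(m$year))
  structure(
    list(target_fraction = target_fraction, threshold = thr,
         derivation_years = years, pooling = pooling),
    class = "threshold_policy")
}

#' Apply a threshold policy to an evaluation year
#'
#' Labels as action nights every night of the evaluation year whose
#' predicted intensity is at least the policy threshold; the capture
#' fraction is their share of the evaluation year's measured passage. No
#' re-optimization happens on the evaluation year. Measured nights with no
#' prediction are treated as below threshold (with a message).
#'
#' @param policy A `threshold_policy` ([derive_threshold()]).
#' @param predicted Nightly predictions for the evaluation year.
#' @param measured `season_series` for the evaluation year.
#' @return A `selection_result` with `method = "forecast_dynamic"`.
#' @export
apply_threshold <- function(policy, predicted, measured) {
  stopifnot(inherits(policy, "threshold_policy"),
            inherits(measured, "season_series"))
  if (measured$year %in% policy$derivation_years)
    stop("validation error: evaluation year ", measured$year,
         " is among the policy's derivation years")
  nights <- complete_nights(measured)
  pred <- as.data.table(predicted)
  m <- pred[nights, on = c("station_id", "night_id")]
  n_missing <- sum(is.na(m$predicted_traffic))
  if (n_missing > 0L) {
    message("apply_threshold: ", n_missing,
            " measured night(s) without prediction treated as below ",
            "threshold")
    m[is.na(predicted_traffic), predicted_traffic := -Inf]
  }
  sel <- m[predicted_traffic >= policy$threshold]
  total <- sum(nights$traffic)
  new_selection_result(
    "forecast_dynamic", measured, sel$night_id,
    capture_fraction = if (total > 0) sum(sel$traffic) / total else 0,
    target_fraction = policy$target_fraction,
    detail = list(threshold = policy$threshold,
                  derivation_years = policy$derivation_years)
  )
}

# per-year traffic vectors on the aligned 1..S season-position grid
season_position_matrix <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  S <- vapply(series_list, function(s)
    length(season_nights(s$season, s$year)), integer(1))
  stopifnot(length(unique(S)) == 1L)
  S <- S[1]
  v <- t(vapply(series_list, function(s) {
    b <- season_bounds(s$season, s$year)
    out <- numeric(S)
    cn <- complete_nights(s)
    pos <- as.integer(cn$night_id - b[["start"]]) + 1L
    out[pos] <- cn$traffic
    out
  }, numeric(S)))
  v
}

#' Optimal fixed conservation window from past years
#'
#' Exhaustively searches window widths 1..`max_width` nights and every
#' feasible start position within the season. For each (width, start) pair
#' the within-window share of each derivation year's measured passage is
#' computed and averaged across years; the minimum-width window whose mean
#' capture reaches `target_fraction` wins. Among equal widths the start
#' maximizing mean capture wins; remaining ties go to the earliest start.
#' Positions align years by calendar date (offset from the season start).
#'
#' @param series_list List of `season_series` (derivation years, one
#'   station).
#' @param target_fraction Target share, in (0, 1\].
#' @param max_width Largest width searched, nights. Default 100.
#' @return A `fixed_window` list: `start_offset` (0-based nights from the
#'   season start), `width`, `mean_capture`, `target_fraction`, `feasible`
#'   (`FALSE` if no window of width <= `max_width` reaches the target, in
#'   which case the best-capturing widest window is returned with a
#'   warning).
#' @export
optimal_fixed_window <- function(series_list, target_fraction,
                                 max_width = 100L) {
  stopifnot(target_fraction > 0, target_fraction <= 1, max_width >= 1L)
  if (inherits(series_list, "season_series")) series_list <- list(series_list)
  v <- season_position_matrix(series_list)
  S <- ncol(v)
  totals <- rowSums(v)
  if (any(totals <= 0))
    stop("selection undefined: a derivation year has zero total passage")
  cs <- cbind(0, t(apply(v, 1L, cumsum))) # years x (S+1)
  max_width <- min(as.integer(max_width), S)

  best <- NULL
  for (w in seq_len(max_width)) {
    starts <- seq_len(S - w + 1L)
    # capture share per year for every start, then mean across years
    cap <- (cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]) /
      totals
    mean_cap <- colMeans(cap)
    ok <- which(mean_cap >= target_fraction - 1e-12)
    if (length(ok) > 0L) {
      s_best <- ok[which.max(mean_cap[ok])]
      # which.max returns the first (earliest) maximum: ties -> earliest
      best <- list(start = s_best, width = w,
                   mean_capture = mean_cap[s_best], feasible = TRUE)
      break
    }
    if (w == max_width) {
      s_best <- which.max(mean_cap)
      best <- list(start = s_best, width = w,
                   mean_capture = mean_cap[s_best], feasible = FALSE)
      warning("no window of width <= ", max_width, " reaches the target; ",
              "returning the best-capturing width-", max_width, " window")
    }
  }
  structure(
    list(start_offset = best$start - 1L, width = best$width,
         mean_capture = best$mean_capture,
         target_fraction = target_fraction, feasible = best$feasible),
    class = "fixed_window")
}

#' @export
print.fixed_window <- function(x, ...) {
  cat("<fixed_window> width ", x$width, " night(s) starting ",
      x$start_offset, " night(s) after season start; mean derivation ",
      "capture ", sprintf("%.3f", x$mean_capture),
      if (!x$feasible) " (target not reachable)", "\n", sep = "")
  invisible(x)
}

#' Evaluate a fixed window on a held-out year
#'
#' Action nights are all calendar nights in the window (missing-data nights
#' still count toward the width: conservation action would run regardless,
#' but they contribute zero measured capture).
#'
#' @param window A `fixed_window` ([optimal_fixed_window()]).
#' @param measured `season_series` for the evaluation year.
#' @return A `selection_result` with `method = "fixed_window"` and
#'   `n_nights` equal to the window width.
#' @export
evaluate_window <- function(window, measured) {
  stopifnot(inherits(window, "fixed_window"),
            inherits(measured, "season_series"))
  if (window$width < 1L)
    stop("validation error: window width must be at least 1 night")
  b <- season_bounds(measured$season, measured$year)
  start <- b[["start"]] + window$start_offset
  end <- start + window$width - 1L
  if (end > b[["end"]])
    stop("validation error: window extends past the season end")
  nights <- complete_nights(measured)
  total <- sum(nights$traffic)
  inside <- nights[night_id >= start & night_id <= end]
  res <- new_selection_result(
    "fixed_window", measured, seq(start, end, by = "day"),
    capture_fraction = if (total > 0) sum(inside$traffic) / total else 0,
    target_fraction = window$target_fraction,
    detail = list(start = as.character(start), width = window$width,
                  mean_derivation_capture = window$mean_capture,
                  feasible = window$feasible)
  )
  res
}

#' Run all three selection methods under a hold-one-year-out protocol
#'
#' For every station and every valid evaluation year: idealized dynamic
#' selection uses that year's measured traffic; the forecast-dynamic
#' threshold and the fixed window are derived from the remaining valid
#' years and applied to the evaluation year. Stations with fewer than 2
#' valid years are skipped (nothing to derive from).
#'
#' @param seasons Named list of `season_series` ([build_seasons()]).
#' @param predictions Nightly predictions covering all years (e.g.
#'   `loyo_evaluate()$predictions`, where each year is predicted by a model
#'   that never saw it).
#' @param targets Numeric vector of target fractions. Default
#'   `c(0.25, 0.5, 0.75)`.
#' @param max_width Fixed-window width cap. Default 100.
#' @return List of `selection_result` (3 methods x stations x years x
#'   targets).
#' @export
select_all_methods <- function(seasons, predictions,
                               targets = c(0.25, 0.5, 0.75),
                               max_width = 100L) {
  seasons <- Filter(function(s) s$valid, seasons)
  stations <- unique(vapply(seasons, `[[`, character(1), "station_id"))
  pred <- as.data.table(predictions)
  results <- list()
  for (st in stations) {
    st_seasons <- Filter(function(s) s$station_id == st, seasons)
    yrs <- vapply(st_seasons, `[[`, numeric(1), "year")
    if (length(yrs) < 2L) next
    for (i in seq_along(yrs)) {
      eval_series <- st_seasons[[i]]
      deriv <- st_seasons[-i]
      deriv_years <- yrs[-i]
      pred_deriv <- pred[station_id == st &
                           features_year(pred) %in% deriv_years]
      pred_eval <- pred[station_id == st &
                          features_year(pred) == yrs[i]]
      for (tf in targets) {
        results[[length(results) + 1L]] <-
          idealized_dynamic(eval_series, tf)
        pol <- derive_threshold(pred_deriv, deriv, tf)
        results[[length(results) + 1L]] <-
          apply_threshold(pol, pred_eval, eval_series)
        win <- optimal_fixed_window(deriv, tf, max_width)
        results[[length(results) + 1L]] <-
          evaluate_window(win, eval_series)
      }
    }
  }
  results
}
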