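#' Concentration of seasonal passage across nights
#'
#' For each fraction `f`, nights are ranked by measured traffic
#' (descending) and the share of total seasonal passage on the top
#' `ceiling(f * N)` nights is reported. Shares are scale-invariant and
#' monotone non-decreasing in `f`, reaching 1 at `f = 1`.
#'
#' @param series A `season_series` with positive total passage.
#' @param fractions Top-night fractions in (0, 1\]. Default
#'   `seq(0.05, 1, by = 0.05)`.
#' @return `data.table`: `station_id`, `season`, `year`, `fraction`,
#'   `n_top` (nights in the top set), `share`.
#' @export
#' @examples
#' # a 4-night season where one night holds 70% of passage
#' nights <- data.table::data.table(
#'   station_id = "KAAA",
#'   night_id = as.Date("2015-03-01") + 0:3,
#'   traffic = c(70, 10, 10, 10), n_samples = 21L, complete = TRUE
#' )
#' s <- build_season(nights, "spring", 2015, min_nights = 1)
#' concentration_curve(s, fractions = c(0.25, 1))
concentration_curve <- function(series, fractions = seq(0.05, 1, by = 0.05)) {
  stopifnot(inherits(series, "season_series"),
            all(fractions > 0), all(fractions <= 1))
  nights <- complete_nights(series)
  total <- sum(nights$traffic)
  if (!is.finite(total) || total <= 0)
    stop("concentration undefined: total seasonal passage is zero")
  tr <- sort(nights$traffic, decreasing = TRUE)
  cum <- cumsum(tr)
  n_top <- pmin(ceiling(fractions * length(tr)), length(tr))
  data.table(
    station_id = series$station_id, season = series$season,
    year = series$year, fraction = fractions, n_top = as.integer(n_top),
    share = cum[n_top] / total
  )
}

#' Compare two selection methods on matched keys
#'
#' Pairs results of two methods on matched (station, season, year, target)
#' keys, reports the per-key difference in action nights
#' (`method_a - method_b`), its mean and SD, and a two-sided paired t-test.
#' With station coordinates supplied, univariate ordinary-least-squares
#' fits of each method's `n_nights` on latitude and on longitude are also
#' reported (slope, SE, p, 95% CI).
#'
#' @param results List of `selection_result` or a [selection_table()].
#' @param method_a,method_b Method labels to compare.
#' @param target Optional target fraction to restrict to (required when the
#'   results span several targets).
#' @param stations Optional list of [station_config()] for the spatial
#'   fits.
#' @return A `comparison_report` list: `diffs` (per-key table),
#'   `mean_diff`, `sd_diff`, `t_stat`, `df`, `p_value`, `degenerate`
#'   (`TRUE` when the differences have zero variance, making t undefined),
#'   `spatial` (`NULL` or a table of OLS fits).
#' @export
compare_methods <- function(results, method_a, method_b, target = NULL,
                            stations = NULL) {
  tab <- if (is.data.frame(results)) as.data.table(results)
         else selection_table(results)
  if (!is.null(target))
    tab <- tab[abs(target_fraction - target) < 1e-9]
  if (uniqueN(tab$target_fraction) > 1L)
    stop("validation error: results span several targets; pass 'target'")
  key <- c("station_id", "season", "year", "target_fraction")
  a <- tab[method == method_a, c(key, "n_nights", "capture_fraction"),
           with = FALSE]
  b <- tab[method == method_b, c(key, "n_nights", "capture_fraction"),
           with = FALSE]
  m <- merge(a, b, by = key, suffixes = c("_a", "_b"))
  if (nrow(m) < 2L)
    stop("validation error: fewer than 2 matched station-season-year keys")
  m[, diff_nights := n_nights_a - n_nights_b]

  degenerate <- sd(m$diff_nights) == 0
  if (degenerate) {
    # zero-variance differences: t is 0/0; report 0 when the methods are
    # literally identical, undefined otherwise
    t_stat <- if (all(m$diff_nights == 0)) 0 else NA_real_
    p_value <- if (all(m$diff_nights == 0)) 1 else NA_real_
    df <- nrow(m) - 1L
  } else {
    tt <- t.test(m$n_nights_a, m$n_nights_b, paired = TRUE)
    t_stat <- unname(tt$statistic); p_value <- tt$p.value
    df <- unname(tt$parameter)
  }

  spatial <- NULL
  if (!is.null(stations)) {
    coords <- data.table(
      station_id = vapply(stations, `[[`, character(1), "station_id"),
      latitude = vapply(stations, `[[`, numeric(1), "latitude"),
      longitude = vapply(stations, `[[`, numeric(1), "longitude")
    )
    tt2 <- merge(tab[method %in% c(method_a, method_b)], coords,
                 by = "station_id")
    spatial <- rbindlist(lapply(
      split(tt2, tt2$method), function(d) rbindlist(lapply(
        c("latitude", "longitude"), function(pr) {
          fit <- lm(d$n_nights ~ d[[pr]])
          cf <- summary(fit)$coefficients
          ci <- confint(fit)[2, ]
          data.table(method = d$method[1], predictor = pr,
                     slope = cf[2, 1], se = cf[2, 2],
                     p_value = signif(cf[2, 4], 3),
                     ci_lo = ci[1], ci_hi = ci[2])
        }))))
  }

  structure(
    list(method_a = method_a, method_b = method_b, diffs = m,
         mean_diff = mean(m$diff_nights), sd_diff = sd(m$diff_nights),
         t_stat = t_stat, df = df, p_value = p_value,
         degenerate = degenerate, spatial = spatial),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$method_a, " - ", x$method_b, " on ",
      nrow(x$diffs), " matched keys\n", sep = "")
  cat("  mean difference ", sprintf("%.2f", x$mean_diff), " nights (SD ",
      sprintf("%.2f", x$sd_diff), ")\n", sep = "")
  if (x$degenerate) {
    cat("  paired t undefined (zero-variance differences)\n")
  } else {
    cat("  paired t = ", sprintf("%.2f", x$t_stat), ", df = ", x$df,
        ", p = ", signif(x$p_value, 3), "\n", sep = "")
  }
  if (!is.null(x$spatial)) print(x$spatial)
  invisible(x)
}

#' Capture-versus-action-nights curve
#'
#' Aggregates selection results over stations and years: for each method
#' and target fraction, the mean number of action nights and the mean
#' realized capture fraction.
#'
#' @param results List of `selection_result` or a [selection_table()]
#'   spanning a grid of targets (e.g. `seq(0.05, 0.95, by = 0.05)`).
#' @return `data.table`: `method`, `target_fraction`, `mean_n_nights`,
#'   `mean_capture`, `n_keys`, ordered by method and target.
#' @export
capture_curve <- function(results) {
  tab <- if (is.data.frame(results)) as.data.table(results)
         else selection_table(results)
  out <- tab[, .(mean_n_nights = mean(n_nights),
                 mean_capture = mean(capture_fraction),
                 n_keys = .N),
             keyby = .(method, target_fraction)]
  out[]
}
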