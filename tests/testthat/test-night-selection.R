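test_that("idealized selection returns the minimal top-k prefix", {
  s <- make_season(c(50, 30, 10, 5, 5))
  r <- idealized_dynamic(s, 0.5)
  expect_equal(r$n_nights, 1L)
  expect_equal(r$capture_fraction, 0.5)

  s2 <- make_season(c(40, 35, 15, 10))
  r2 <- idealized_dynamic(s2, 0.5)
  expect_equal(r2$n_nights, 2L)
  expect_equal(r2$capture_fraction, 0.75)

  s3 <- make_season(c(0, 0, 100, 0))
  for (tf in c(0.25, 0.5, 1)) {
    r3 <- idealized_dynamic(s3, tf)
    expect_equal(r3$n_nights, 1L)
    expect_equal(r3$capture_fraction, 1.0)
  }
  expect_error(idealized_dynamic(make_season(c(0, 0, 0)), 0.5), "zero")
})

test_that("ties in traffic break toward the earlier date", {
  s <- make_season(c(10, 40, 40, 10))
  r <- idealized_dynamic(s, 0.4)
  expect_equal(r$action_nights, s$nights$night_id[2])
})

test_that("idealized night counts match the exhaustive-subset oracle", {
  set.seed(11)
  for (i in 1:20) {
    traffic <- runif(10, 0, 100)
    s <- make_season(traffic)
    for (tf in c(0.25, 0.5, 0.75)) {
      expect_equal(idealized_dynamic(s, tf)$n_nights,
                   oracle_min_nights(traffic, tf))
    }
  }
})

test_that("threshold derivation picks the largest qualifying candidate", {
  meas <- make_season(c(10, 20, 30, 40), year = 2014)
  pred <- make_predictions(c(10, 20, 30, 40), year = 2014)
  pol <- derive_threshold(pred, list(meas), 0.5)
  expect_equal(pol$threshold, 30) # {30, 40} capture 0.70; t = 40 only 0.40

  # an order-preserving miscalibration selects the same nights
  pol2 <- derive_threshold(make_predictions(2 * c(10, 20, 30, 40),
                                            year = 2014),
                           list(meas), 0.5)
  expect_equal(pol2$threshold, 60)

  # target 1 forces every positive night in: smallest candidate
  pol3 <- derive_threshold(pred, list(meas), 1.0)
  expect_equal(pol3$threshold, 10)
})

test_that("threshold application scores with measured passage only", {
  meas <- make_season(c(10, 50, 40), year = 2017)
  pred <- make_predictions(c(5, 35, 25), year = 2017)
  pol <- structure(list(target_fraction = 0.5, threshold = 30,
                        derivation_years = 2014:2016, pooling = "pooled"),
                   class = "threshold_policy")
  r <- apply_threshold(pol, pred, meas)
  expect_equal(r$n_nights, 1L)
  expect_equal(r$capture_fraction, 0.5)

  pol_hi <- structure(list(target_fraction = 0.5, threshold = 1e9,
                           derivation_years = 2014:2016,
                           pooling = "pooled"),
                      class = "threshold_policy")
  r2 <- apply_threshold(pol_hi, pred, meas)
  expect_equal(r2$n_nights, 0L)
  expect_equal(r2$capture_fraction, 0)

  # evaluation year must be held out of the derivation set
  pol_bad <- structure(list(target_fraction = 0.5, threshold = 30,
                            derivation_years = 2016:2017,
                            pooling = "pooled"),
                       class = "threshold_policy")
  expect_error(apply_threshold(pol_bad, pred, meas), "derivation")
})

test_that("a threshold derived from perfect predictions meets its target", {
  set.seed(21)
  traffic <- pulsed_traffic(60)
  deriv <- make_season(traffic, year = 2014)
  eval_s <- make_season(traffic, year = 2015) # identical twin year
  pol <- derive_threshold(make_predictions(traffic, year = 2014),
                          list(deriv), 0.5)
  r <- apply_threshold(pol, make_predictions(traffic, year = 2015), eval_s)
  expect_gte(r$capture_fraction, 0.5)
  expect_equal(r$n_nights, idealized_dynamic(eval_s, 0.5)$n_nights)
})

test_that("fixed-window search returns the minimum qualifying width", {
  s <- make_season(c(0, 10, 40, 40, 10, 0))
  w <- optimal_fixed_window(list(s), 0.5)
  expect_equal(w$width, 2L)
  expect_equal(w$start_offset, 2L) # third night of the season
  expect_equal(w$mean_capture, 0.8)

  u <- make_season(rep(10, 10))
  wu <- optimal_fixed_window(list(u), 0.5)
  expect_equal(wu$width, 5L)
  expect_equal(wu$start_offset, 0L) # earliest of the tied starts

  # two years with disjoint single-night peaks 10 nights apart: a window
  # on either peak alone has mean capture 0.5 across the two years, so
  # only targets above 0.5 force the window to span both peaks
  y1 <- make_season(c(100, rep(0, 10)), year = 2014)
  y2 <- make_season(c(rep(0, 10), 100), year = 2015)
  expect_equal(optimal_fixed_window(list(y1, y2), 0.5)$width, 1L)
  w2 <- optimal_fixed_window(list(y1, y2), 0.75)
  expect_equal(w2$width, 11L)
  expect_equal(w2$mean_capture, 1.0)
})

test_that("fixed-window search matches the brute-force oracle", {
  set.seed(41)
  for (i in 1:30) {
    v <- matrix(runif(3 * 40, 0, 100), nrow = 3)
    series <- lapply(1:3, function(y)
      make_season(v[y, ], year = 2013 + y))
    tf <- sample(c(0.25, 0.5, 0.75), 1)
    got <- optimal_fixed_window(series, tf)
    want <- oracle_fixed_window(v, tf)
    expect_equal(got$width, want$width)
    expect_equal(got$start_offset + 1L, want$start)
    expect_equal(got$mean_capture, want$mean_capture)
  }
})

test_that("window evaluation counts calendar nights and season-wide capture", {
  s <- make_season(pulsed_traffic(30))
  full <- structure(list(start_offset = 0L, width = 30L, mean_capture = 1,
                         target_fraction = 0.5, feasible = TRUE),
                    class = "fixed_window")
  r <- evaluate_window(full, s)
  expect_equal(r$capture_fraction, 1.0)
  expect_equal(r$n_nights, 30L)
  zero <- structure(list(start_offset = 0L, width = 0L, mean_capture = 0,
                         target_fraction = 0.5, feasible = TRUE),
                    class = "fixed_window")
  expect_error(evaluate_window(zero, s), "width")
  # missing nights inside the window still count toward its width
  nights <- copy(s$nights)[5, complete := FALSE]
  s_gap <- build_season(nights, "spring", 2015, min_nights = 1L)
  r_gap <- evaluate_window(full, s_gap)
  expect_equal(r_gap$n_nights, 30L)
  expect_equal(r_gap$capture_fraction, 1.0) # share of measured passage
})

test_that("action nights grow monotonically with the target fraction", {
  set.seed(51)
  traffic <- pulsed_traffic(80)
  s <- make_season(traffic, year = 2015)
  deriv <- make_season(pulsed_traffic(80), year = 2014)
  noisy_pred <- traffic * exp(rnorm(80, sd = 0.4))
  pred_d <- make_predictions(deriv$nights$traffic * exp(rnorm(80, sd = 0.4)),
                             year = 2014)
  pred_e <- make_predictions(noisy_pred, year = 2015)
  grid <- seq(0.1, 0.9, by = 0.1)
  n_ideal <- vapply(grid, function(tf)
    idealized_dynamic(s, tf)$n_nights, integer(1))
  n_fore <- vapply(grid, function(tf) {
    pol <- derive_threshold(pred_d, list(deriv), tf)
    apply_threshold(pol, pred_e, s)$n_nights
  }, integer(1))
  n_fixed <- vapply(grid, function(tf)
    optimal_fixed_window(list(deriv), tf)$width, integer(1))
  expect_true(all(diff(n_ideal) >= 0))
  expect_true(all(diff(n_fore) >= 0))
  expect_true(all(diff(n_fixed) >= 0))
})

test_that("lowering a threshold never removes an action night", {
  set.seed(61)
  s <- make_season(pulsed_traffic(60), year = 2017)
  pred <- make_predictions(pulsed_traffic(60), year = 2017)
  mk_pol <- function(t) structure(
    list(target_fraction = 0.5, threshold = t,
         derivation_years = 2014:2016, pooling = "pooled"),
    class = "threshold_policy")
  thr <- sort(unique(pred$predicted_traffic))[c(10, 25, 40)]
  sets <- lapply(thr, function(t)
    apply_threshold(mk_pol(t), pred, s)$action_nights)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("idealized selection dominates both other methods", {
  set.seed(71)
  for (i in 1:10) {
    traffic <- pulsed_traffic(60)
    s <- make_season(traffic, year = 2015)
    deriv <- make_season(pulsed_traffic(60), year = 2014)
    pol <- derive_threshold(
      make_predictions(deriv$nights$traffic * exp(rnorm(60, sd = 0.5)),
                       year = 2014), list(deriv), 0.5)
    fore <- apply_threshold(
      pol, make_predictions(traffic * exp(rnorm(60, sd = 0.5)),
                            year = 2015), s)
    win <- evaluate_window(optimal_fixed_window(list(deriv), 0.5), s)
    if (fore$capture_fraction > 0)
      expect_lte(idealized_dynamic(s, fore$capture_fraction)$n_nights,
                 fore$n_nights)
    if (win$capture_fraction > 0)
      expect_lte(idealized_dynamic(s, win$capture_fraction)$n_nights,
                 win$n_nights)
  }
})
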