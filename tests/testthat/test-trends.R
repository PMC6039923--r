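test_that("OLS trends handle exact, symmetric and degenerate series", {
  line <- annual_series(2000:2009, 1.5 * (2000:2009) - 2900)
  f <- linear_trend(line)
  expect_equal(f$slope, 1.5, tolerance = 1e-12)
  expect_equal(abs(f$r), 1)
  expect_equal(f$mse, 0, tolerance = 1e-18)
  expect_equal(f$p_value, 0)

  sym <- linear_trend(annual_series(1990:1992, c(0, 1, 0)))
  expect_equal(sym$slope, 0, tolerance = 1e-12)
  expect_equal(sym$r, 0)
  expect_equal(sym$intercept, 1 / 3, tolerance = 1e-9)  # slope 0: intercept is the mean

  flat <- linear_trend(annual_series(1990:1995, rep(2, 6)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)
  expect_equal(flat$p_value, 1)

  expect_error(linear_trend(annual_series(1990:1991, c(1, 2))),
               class = "lifelimits_insufficient_data")
  expect_error(linear_trend(line, window = c(1900, 1901)),
               class = "lifelimits_insufficient_data")
})

test_that("trend fits are equivariant under value shifts and added linear drift", {
  set.seed(42)
  base <- annual_series(1960:1990, rnorm(31))
  f0 <- linear_trend(base)
  f_shift <- linear_trend(annual_series(base$year, base$value + 7))
  expect_equal(f_shift$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f_shift$intercept, f0$intercept + 7, tolerance = 1e-9)
  f_drift <- linear_trend(annual_series(base$year, base$value + 0.3 * base$year))
  expect_equal(f_drift$slope, f0$slope + 0.3, tolerance = 1e-12)
  expect_equal(f_drift$mse, f0$mse, tolerance = 1e-9)
  # exclusion by year removes exactly those points
  f_ex <- linear_trend(base, exclude_years = 1975:1980)
  expect_equal(f_ex$n, 25)
})

test_that("survival gain rates are zero without improvement and error on empty windows", {
  flat <- make_improving_series(gompertz_params(6e-5, 0.1), annual_decline = 0,
                                years = 1950:1960)
  f <- survival_change_rate(flat, age = 100)
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_error(survival_change_rate(flat, age = 100, window = c(1800, 1805)),
               class = "lifelimits_insufficient_data")
  expect_error(survival_change_rate(flat, age = 200),
               class = "lifelimits_age_absent")
})

test_that("rounding plus log(0)=log(1) attenuates the late-life gain rate", {
  exact <- make_improving_series(gompertz_params(6e-5, 0.1), years = 1900:1990)
  rounded <- lapply(exact, apply_integer_rounding)
  drop_exact <- survival_change_rate(exact, 105, "drop")
  asone_rounded <- survival_change_rate(rounded, 105, "as_one")
  expect_gt(drop_exact$slope, 0)
  expect_lt(asone_rounded$slope, drop_exact$slope)
  # with only zeros dropped instead, the surviving points stay informative
  drop_rounded <- survival_change_rate(rounded, 105, "drop")
  expect_gt(drop_rounded$slope, asone_rounded$slope)
})

test_that("the age of greatest gain is bounded by a terminal cap", {
  series <- make_improving_series(gompertz_params(6e-5, 0.1),
                                  years = 1900:1950, max_age = 120)
  capped <- lapply(series, apply_age_cap, cap = 110)
  uncapped_best <- age_of_greatest_gain(series, ages = 90:120)
  capped_best <- age_of_greatest_gain(capped, ages = 90:120)
  expect_gt(as.numeric(uncapped_best), 110)
  expect_lte(as.numeric(capped_best), 110)
  # no improvement: every slope ~0, maximum is degenerate
  flat <- make_improving_series(gompertz_params(6e-5, 0.1), annual_decline = 0,
                                years = 1950:1960)
  expect_warning(age_of_greatest_gain(flat, ages = 95:105),
                 class = "lifelimits_degenerate_maximum")
})

test_that("annual extremes are proper order statistics of the record panel", {
  rec <- tibble::tibble(
    record_id = c("A", "B", "C", "D"),
    age_at_death = c(122.45, 111, 113, 112),
    death_year = c(1997L, 1997L, 1998L, 1998L),
    death_month = c(8L, 1L, 2L, 3L),
    death_day = NA_integer_,
    country = c("FRA", "FRA", "USA", "USA"),
    validation_status = "validated")
  top1 <- annual_extreme(rec, rank = 1)
  expect_equal(top1$value, c(122.45, 113))
  top2 <- annual_extreme(rec, rank = 2)
  expect_equal(top2$value, c(111, 112))
  top3 <- annual_extreme(rec, rank = 3)
  expect_equal(nrow(top3), 0)           # years with < k records are omitted
  expect_true(all(top1$value >= top2$value))
  by_ctry <- annual_extreme(rec, rank = 1, by_country = TRUE)
  expect_named(by_ctry, c("FRA", "USA"))
  expect_equal(by_ctry$FRA$value, 122.45)
  expect_error(annual_extreme(rec, rank = 0), class = "lifelimits_parameter")
  expect_error(annual_extreme(rec[0, ]), class = "lifelimits_validation")
  mean_rad <- annual_mean_rad(rec)
  expect_equal(mean_rad$value, c(mean(c(122.45, 111)), mean(c(113, 112))))
})

test_that("segmented trends split at the breakpoint and report absent sides", {
  line <- annual_series(1980:2005, 0.2 * (1980:2005) - 300)
  seg <- segmented_trend(line, 1995)
  expect_equal(seg$pre$slope, seg$post$slope, tolerance = 1e-9)
  expect_equal(seg$pre$window[2], 1994)
  expect_equal(seg$post$window[1], 1995)
  short <- annual_series(1994:2000, c(1, 2, 1, 2, 1, 2, 1))
  seg2 <- segmented_trend(short, 1995)
  expect_null(seg2$pre)
  expect_match(seg2$reasons["pre"], "1 point")
  expect_false(is.null(seg2$post))
})

test_that("record filters compose commutatively", {
  rec <- simulate_record_panel(test_panel_spec(6, 4), seed = 13)
  may_june <- filter_records(rec, exclude_months = c(5, 6))
  expect_true(all(!may_june$death_month %in% c(5, 6)))
  expect_equal(nrow(may_june), sum(!rec$death_month %in% c(5, 6)))
  one_out <- filter_records(rec, exclude_ids = rec$record_id[1])
  expect_equal(nrow(one_out), nrow(rec) - 1)
  a <- filter_records(filter_records(rec, exclude_months = c(5, 6)),
                      countries = "BIG", window = c(1990, 2000))
  b <- filter_records(filter_records(rec, window = c(1990, 2000),
                                     countries = "BIG"),
                      exclude_months = c(5, 6))
  expect_equal(a, b)
  expect_equal(nrow(filter_records(rec, countries = "NONE")), 0)
})

test_that("LOWESS reproduces lines and constants and matches the closed-form window fit", {
  years <- 2000:2014
  line <- annual_series(years, 0.7 * years - 1000)
  expect_equal(lowess_smooth(line)$value, line$value, tolerance = 1e-9)
  expect_equal(lowess_smooth(line)$year, line$year)
  const <- annual_series(years, rep(3.2, 15))
  expect_equal(lowess_smooth(const)$value, const$value, tolerance = 1e-12)

  # interior point against a hand-computed tricube-weighted regression
  x <- c(2000, 2001, 2003, 2006, 2010, 2011, 2012)
  y <- c(1.0, 1.4, 0.9, 1.8, 2.5, 2.2, 2.9)
  s <- annual_series(x, y)
  sm <- lowess_smooth(s, span = 3 / 7, robust_iterations = 0)
  # window of the 3 nearest neighbours of 2006: {2003, 2006, 2010}, h = 4
  xi <- c(2003, 2006, 2010); yi <- y[match(xi, x)]
  w <- (1 - (abs(xi - 2006) / 4)^3)^3
  X <- cbind(1, xi)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * yi))
  expect_equal(sm$value[4], drop(c(1, 2006) %*% beta), tolerance = 1e-9)

  # a tiny span widens the window to 2 points with a warning
  expect_warning(lowess_smooth(s, span = 0.05, robust_iterations = 0),
                 class = "lifelimits_small_window")
  # independent cross-check against the classical implementation
  set.seed(8)
  yy <- sin(seq(0, 3, length.out = 40)) + rnorm(40, 0, 0.05)
  mine <- lowess_smooth(annual_series(1961:2000, yy), span = 0.5,
                        robust_iterations = 0)
  ref <- stats::lowess(1961:2000, yy, f = 0.5, iter = 0, delta = 0)
  expect_equal(mine$value, ref$y, tolerance = 1e-6)
})
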