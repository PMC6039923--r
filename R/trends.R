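#' Construct an annual series
#'
#' An ordered set of `(year, value)` pairs with unique, strictly
#' increasing years and finite values — the common currency of the trend
#' analyses (MRAD by year, log-survival by year, ...).
#'
#' @param year Calendar years.
#' @param value Numeric values.
#' @return A data frame of class `annual_series`.
#' @export
annual_series <- function(year, value) {
  if (length(year) != length(value))
    ll_abort("year and value must have equal length", "lifelimits_validation")
  o <- order(year)
  year <- as.integer(year[o]); value <- as.numeric(value[o])
  if (anyDuplicated(year))
    ll_abort("years must be unique", "lifelimits_validation")
  if (any(!is.finite(value)))
    ll_abort("series values must be finite", "lifelimits_validation")
  structure(data.frame(year = year, value = value),
            class = c("annual_series", "data.frame"))
}

as_annual_series <- function(x) {
  if (inherits(x, "annual_series")) return(x)
  if (is.data.frame(x) && all(c("year", "value") %in% names(x)))
    return(annual_series(x$year, x$value))
  ll_abort("expected an annual_series or a data frame with year and value",
           "lifelimits_validation")
}

window_series <- function(series, window = NULL, exclude_years = NULL) {
  keep <- rep(TRUE, nrow(series))
  if (!is.null(window))
    keep <- keep & series$year >= window[1] & series$year <= window[2]
  if (!is.null(exclude_years))
    keep <- keep & !(series$year %in% exclude_years)
  series[keep, , drop = FALSE]
}

#' Ordinary least-squares trend of an annual series
#'
#' Unweighted OLS of value on calendar year. Reports the slope (value
#' units per year), intercept (at year 0), Pearson correlation `r`, the
#' two-sided p-value of the slope from its t statistic on `n - 2` degrees
#' of freedom, and the mean squared residual `mse` (`sum(res^2)/n`).
#' A series with zero value-variance gets `r = 0`, slope 0 and `p = 1`;
#' an exactly collinear series gets `|r| = 1`, `mse = 0` and `p = 0`.
#'
#' @param series An [annual_series] (or data frame with `year`, `value`).
#' @param window Optional `c(start, end)` calendar-year range (inclusive).
#' @param exclude_years Optional years to drop before fitting.
#' @return An object of class `trend_fit` with fields `slope`,
#'   `intercept`, `r`, `p_value`, `mse`, `n`, `window`.
#' @export
#' @examples
#' linear_trend(annual_series(1990:1992, c(0, 1, 0)))$slope  # 0 by symmetry
linear_trend <- function(series, window = NULL, exclude_years = NULL) {
  series <- window_series(as_annual_series(series), window, exclude_years)
  n <- nrow(series)
  if (n < 3)
    ll_abort(sprintf("need at least 3 points for a trend; have %d", n),
             "lifelimits_insufficient_data")
  x <- series$year; y <- series$value
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  syy <- sum((y - ym)^2)
  sxy <- sum((x - xm) * (y - ym))
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  mse <- sse / n
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  if (syy == 0) {
    p <- 1
  } else if (sse <= 1e-14 * syy) {   # numerically exact fit
    p <- if (slope == 0) 1 else 0
  } else {
    se_slope <- sqrt(sse / (n - 2) / sxx)
    tval <- slope / se_slope
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(slope = slope, intercept = intercept, r = r, p_value = p,
                 mse = mse, n = n, window = range(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %d-%d (n = %d): slope %.4g/y, r = %.3f, p = %.3g, MSE = %.3g\n",
              x$window[1], x$window[2], x$n, x$slope, x$r, x$p_value, x$mse))
  invisible(x)
}

#' @export
as.data.frame.trend_fit <- function(x, ...) {
  data.frame(window_start = x$window[1], window_end = x$window[2],
             slope = x$slope, intercept = x$intercept, r = x$r,
             p = x$p_value, mse = x$mse, n = x$n)
}

#' Annual rate of change in late-life survival at one age
#'
#' Across an ordered collection of life tables, regresses
#' `log(lx[age]/radix)` on calendar year: the slope is the annual gain in
#' log-survival to that age. Zero cells (which integer-rounded tables
#' produce in quantity at high ages) are handled through
#' [log_survival()]'s explicit policy — `drop` removes them, `as_one`
#' treats them as `log(1)` and reproduces the attenuation artifact.
#'
#' @param tables List of [lifetable]s with `index_year` set.
#' @param age Age in completed years; must be present in the tables.
#' @param zero_policy Passed to [log_survival()].
#' @param window Optional calendar-year range.
#' @return A `trend_fit` with attributes `age` and `n_dropped` (points
#'   removed by the zero policy).
#' @export
survival_change_rate <- function(tables, age, zero_policy = "drop",
                                 window = NULL) {
  if (is_lifetable(tables)) tables <- list(tables)
  years <- vapply(tables, function(t) t$index_year, integer(1))
  if (any(is.na(years)))
    ll_abort("every table needs an index_year", "lifelimits_validation")
  props <- vapply(tables, function(t) {
    v <- lx_at(t, age)
    if (length(v) == 0) NA_real_ else v / t$radix
  }, numeric(1))
  absent <- vapply(tables, function(t) !(age %in% t$ages), logical(1))
  if (any(absent))
    ll_abort(sprintf("age %g absent from %d table(s)", age, sum(absent)),
             "lifelimits_age_absent")
  keep <- if (is.null(window)) rep(TRUE, length(years))
          else years >= window[1] & years <= window[2]
  years <- years[keep]; props <- props[keep]
  if (length(years) < 3)
    ll_abort("fewer than 3 tables inside the window", "lifelimits_insufficient_data")
  ls <- log_survival(props, zero_policy)
  if (length(ls$kept) < 3)
    ll_abort(sprintf("only %d usable points at age %g after zero policy '%s'",
                     length(ls$kept), age, zero_policy),
             "lifelimits_insufficient_data")
  fit <- linear_trend(annual_series(years[ls$kept], ls$log))
  attr(fit, "age") <- age
  attr(fit, "n_dropped") <- length(years) - length(ls$kept)
  fit
}

#' Age at which late-life survival gains are greatest
#'
#' Evaluates [survival_change_rate()] at every candidate age present in
#' the tables and returns the age with the largest gain slope, breaking
#' ties toward the older age. Candidate ages absent from the tables
#' (e.g. above a terminal cap) are skipped — which is why an editorial
#' age cap mechanically bounds the answer at the cap. When all slopes
#' are indistinguishable a degenerate-maximum warning is raised.
#'
#' @param tables List of [lifetable]s.
#' @param ages Candidate ages (default 80 to the tables' common maximum).
#' @inheritParams survival_change_rate
#' @return The winning age, with the per-age slopes attached as attribute
#'   `slopes`.
#' @export
age_of_greatest_gain <- function(tables, ages = NULL, zero_policy = "drop",
                                 window = NULL) {
  if (is_lifetable(tables)) tables <- list(tables)
  if (is.null(ages)) {
    top <- min(vapply(tables, function(t) max(t$ages), numeric(1)))
    ages <- 80:top
  }
  slopes <- rep(NA_real_, length(ages))
  for (i in seq_along(ages)) {
    fit <- tryCatch(
      survival_change_rate(tables, ages[i], zero_policy, window),
      lifelimits_age_absent = function(e) NULL)
    if (!is.null(fit)) slopes[i] <- fit$slope
  }
  if (all(is.na(slopes)))
    ll_abort("no candidate age is present in all tables", "lifelimits_insufficient_data")
  ok <- which(!is.na(slopes))
  rng <- range(slopes[ok])
  if (diff(rng) < 1e-10 || max(abs(slopes[ok])) < 1e-10)
    ll_warn("gain slopes are indistinguishable across candidate ages; the maximum is degenerate",
            "lifelimits_degenerate_maximum")
  best <- ok[slopes[ok] == max(slopes[ok])]
  out <- max(ages[best])   # ties broken toward the older age
  attr(out, "slopes") <- stats::setNames(slopes, ages)
  out
}

#' Annual k-th largest reported age at death
#'
#' Per calendar year of death (and per country when `by_country`), the
#' k-th largest age at death among the records; `rank = 1` is the MRAD
#' series. Years with fewer than `rank` records are omitted, not padded.
#' Ties in age occupy consecutive ranks, stable by record id.
#'
#' @param records Death-record tibble.
#' @param rank Order statistic `k >= 1`.
#' @param by_country Split by country?
#' @return An [annual_series]; with `by_country`, a named list of them.
#' @export
annual_extreme <- function(records, rank = 1, by_country = FALSE) {
  records <- validate_death_records(records)
  if (!is.numeric(rank) || rank < 1 || rank != floor(rank))
    ll_abort("'rank' must be an integer >= 1", "lifelimits_parameter")
  if (nrow(records) == 0)
    ll_abort("no death records supplied", "lifelimits_validation")
  kth <- function(df) {
    o <- order(-df$age_at_death, df$record_id)
    years <- split(seq_len(nrow(df)), df$death_year)
    vals <- vapply(years, function(i) {
      a <- df$age_at_death[i][order(-df$age_at_death[i], df$record_id[i])]
      if (length(a) >= rank) a[rank] else NA_real_
    }, numeric(1))
    keep <- !is.na(vals)
    annual_series(as.integer(names(years))[keep], vals[keep])
  }
  if (by_country) {
    lapply(split(records, records$country), kth)
  } else {
    kth(records)
  }
}

#' Annual mean reported age at death
#'
#' Mean age at death per calendar year (the RAD series), the less
#' extreme-value-sensitive companion of [annual_extreme()].
#'
#' @inheritParams annual_extreme
#' @return An [annual_series]; with `by_country`, a named list of them.
#' @export
annual_mean_rad <- function(records, by_country = FALSE) {
  records <- validate_death_records(records)
  if (nrow(records) == 0)
    ll_abort("no death records supplied", "lifelimits_validation")
  avg <- function(df) {
    v <- tapply(df$age_at_death, df$death_year, mean)
    annual_series(as.integer(names(v)), as.numeric(v))
  }
  if (by_country) lapply(split(records, records$country), avg) else avg(records)
}

#' Independent linear trends before and after a breakpoint year
#'
#' Fits [linear_trend()] separately to years strictly before the
#' breakpoint and to years at or after it. A side with fewer than 3
#' points is reported absent (with the reason), never fabricated.
#'
#' @param series An [annual_series].
#' @param breakpoint_year The split year (post side includes it).
#' @return A list of class `segmented_trend` with elements `pre`, `post`
#'   (each a `trend_fit` or `NULL`), `breakpoint` and `reasons`.
#' @export
segmented_trend <- function(series, breakpoint_year) {
  series <- as_annual_series(series)
  fit_side <- function(side) {
    tryCatch(linear_trend(side),
             lifelimits_insufficient_data = function(e) NULL)
  }
  pre_df <- series[series$year < breakpoint_year, , drop = FALSE]
  post_df <- series[series$year >= breakpoint_year, , drop = FALSE]
  pre <- fit_side(pre_df); post <- fit_side(post_df)
  reasons <- c(
    pre = if (is.null(pre)) sprintf("only %d point(s) before %d", nrow(pre_df), breakpoint_year) else NA,
    post = if (is.null(post)) sprintf("only %d point(s) from %d on", nrow(post_df), breakpoint_year) else NA)
  structure(list(pre = pre, post = post, breakpoint = breakpoint_year,
                 reasons = reasons),
            class = "segmented_trend")
}

#' @export
print.segmented_trend <- function(x, ...) {
  cat(sprintf("<segmented_trend> breakpoint %d\n", x$breakpoint))
  for (side in c("pre", "post")) {
    f <- x[[side]]
    if (is.null(f)) cat(sprintf("  %s: absent (%s)\n", side, x$reasons[side]))
    else cat(sprintf("  %s: slope %.4g/y, r = %.3f, p = %.3g, n = %d\n",
                     side, f$slope, f$r, f$p_value, f$n))
  }
  invisible(x)
}

#' Filter death records by country, month, id and death-year window
#'
#' Removes records failing any of the given predicates. The filters
#' commute, so composition order never matters. Month exclusion exists
#' because one reconstruction of the GRG world's-oldest-person series is
#' only matched after removing all May and June deaths; id exclusion
#' supports leave-one-out checks such as removing Jeanne Calment.
#'
#' @param records Death-record tibble.
#' @param countries Keep only these countries (`NULL` = all).
#' @param exclude_months Month numbers (1-12) to remove.
#' @param exclude_ids Record ids to remove.
#' @param window Death-year range `c(start, end)` to keep.
#' @return The filtered tibble (possibly empty).
#' @export
filter_records <- function(records, countries = NULL, exclude_months = NULL,
                           exclude_ids = NULL, window = NULL) {
  records <- validate_death_records(records)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(countries)) keep <- keep & records$country %in% countries
  if (!is.null(exclude_months)) keep <- keep & !(records$death_month %in% exclude_months)
  if (!is.null(exclude_ids)) keep <- keep & !(records$record_id %in% exclude_ids)
  if (!is.null(window)) keep <- keep & records$death_year >= window[1] &
      records$death_year <= window[2]
  records[keep, , drop = FALSE]
}

#' Robust LOWESS smoothing of an annual series
#'
#' At each year, a degree-1 local regression over the `ceiling(span * n)`
#' nearest neighbours with tricube distance weights, followed by the
#' stated number of bisquare robustness iterations (residual-based
#' weights that discount outliers). Output years equal input years. A
#' span so small that a window holds fewer than 2 points is widened to 2
#' with a warning.
#'
#' @param series An [annual_series].
#' @param span Fraction of points in each local window, in `(0, 1]`
#'   (default 0.67).
#' @param robust_iterations Bisquare reweighting passes (default 3).
#' @return An [annual_series] of smoothed values.
#' @export
#' @examples
#' s <- annual_series(2000:2009, 2 * (2000:2009) - 100)
#' all.equal(lowess_smooth(s)$value, s$value)  # a line is reproduced
lowess_smooth <- function(series, span = 0.67, robust_iterations = 3) {
  series <- as_annual_series(series)
  n <- nrow(series)
  if (n < 3)
    ll_abort("need at least 3 points to smooth", "lifelimits_insufficient_data")
  if (!is.numeric(span) || span <= 0 || span > 1)
    ll_abort("'span' must be in (0, 1]", "lifelimits_parameter")
  x <- as.numeric(series$year); y <- series$value
  q <- ceiling(span * n)
  if (q < 2) {
    ll_warn("span gives windows of fewer than 2 points; widening to 2",
            "lifelimits_small_window")
    q <- 2L
  }
  rw <- rep(1, n)
  fitted <- y
  for (it in 0:robust_iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      qi <- q
      repeat {
        idx <- order(d)[seq_len(qi)]
        h <- max(d[idx])
        w <- if (h > 0) (1 - pmin(1, d[idx] / h)^3)^3 else rep(1, qi)
        w <- w * rw[idx]
        if (sum(w > 0) >= 2 || qi >= n) break
        qi <- qi + 1L
      }
      if (sum(w > 0) < 2) w <- (1 - pmin(1, d[idx] / max(h, 1))^3)^3
      fitted[i] <- wls_predict(x[idx], y[idx], w, x[i])
    }
    if (it == robust_iterations) break
    res <- y - fitted
    s <- stats::median(abs(res))
    if (s <= 0) break
    u <- res / (6 * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  annual_series(series$year, fitted)
}

# weighted degree-1 least squares prediction at x0
wls_predict <- function(x, y, w, x0) {
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  if (sxx <= .Machine$double.eps * sum(w * x^2 + 1)) return(ym)
  beta <- sum(w * (x - xm) * (y - ym)) / sxx
  ym + beta * (x0 - xm)
}
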