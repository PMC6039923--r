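#' Fit a log-linear model to age-specific death probabilities
#'
#' Ordinary least squares of `log(qx)` on age over an age window — the
#' core regression from which the maximum survivable age is projected.
#' Ages with `qx >= 1` are always excluded (their log is not informative
#' about the rise towards 1, and the terminal open interval has `qx = 1`
#' by construction); ages with `qx = 0` follow the explicit
#' [log_survival()] zero policy; missing `qx` cells are never treated as
#' zeros.
#'
#' The default window of 40-95 years covers the span where adult human
#' mortality is closest to log-linear: below ~40, infant mortality and
#' the early-adult accident hump bend the curve; above ~95,
#' integer-rounded data degenerate into zeros. The window is always
#' recorded in the fit.
#'
#' @param lt A [lifetable].
#' @param age_window `c(min_age, max_age)`, inclusive (default `c(40, 95)`).
#' @param zero_policy `"drop"` (default), `"as_one"` or `"fail"`.
#' @return An object of class `loglinear_fit`: `intercept` (log q at age
#'   0), `slope` (per-year increase in log q), `r2`, `se_intercept`,
#'   `se_slope`, `cov_si`, `n_ages`, `age_window`, plus the table's
#'   identifying metadata.
#' @export
#' @examples
#' lt <- make_loglinear_q_table(gompertz_params(1e-4, 0.1))
#' f <- fit_loglinear_mortality(lt)
#' c(f$slope, exp(f$intercept))   # recovers b = 0.1 and a = 1e-4
fit_loglinear_mortality <- function(lt, age_window = c(40, 95),
                                    zero_policy = "drop") {
  validate_lifetable(lt)
  sel <- lt$ages >= age_window[1] & lt$ages <= age_window[2]
  if (lt$open_interval) sel[length(sel)] <- FALSE   # terminal interval excluded
  sel <- sel & !is.na(lt$qx) & lt$qx < 1
  ages <- lt$ages[sel]
  q <- lt$qx[sel]
  ls <- log_survival(q, zero_policy)
  ages <- ages[ls$kept]; logq <- ls$log
  if (length(ages) < 3)
    ll_abort(sprintf("only %d usable ages in window [%g, %g]",
                     length(ages), age_window[1], age_window[2]),
             "lifelimits_insufficient_data")
  fit <- stats::lm(logq ~ ages)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  if (!is.finite(slope) || slope <= 0)
    ll_abort(sprintf("fitted slope %.3g is not positive: mortality is not increasing log-linearly, MSA undefined",
                     slope), "lifelimits_nonprojectable")
  res <- stats::residuals(fit)
  n <- length(ages)
  sigma2 <- sum(res^2) / (n - 2)          # avoids summary.lm's perfect-fit warning
  X <- cbind(1, ages)
  V <- sigma2 * solve(crossprod(X))
  ssy <- sum((logq - mean(logq))^2)
  r2 <- if (ssy == 0) 1 else 1 - sum(res^2) / ssy
  structure(list(intercept = intercept, slope = slope,
                 r2 = min(max(r2, 0), 1),
                 se_intercept = sqrt(max(V[1, 1], 0)),
                 se_slope = sqrt(max(V[2, 2], 0)),
                 cov_si = V[1, 2],
                 n_ages = length(ages),
                 age_window = c(min(ages), max(ages)),
                 population_id = lt$population_id,
                 index_year = lt$index_year,
                 table_type = lt$table_type),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> %s %s %s: log q = %.4f + %.5f * age (R2 = %.4f, n = %d, ages %d-%d)\n",
              x$population_id, x$table_type,
              ifelse(is.na(x$index_year), "", x$index_year),
              x$intercept, x$slope, x$r2, x$n_ages,
              x$age_window[1], x$age_window[2]))
  invisible(x)
}

#' Project a log-linear mortality fit to q = 1
#'
#' The maximum survivable age is the age at which the fitted line
#' `log q = intercept + slope * age` reaches `log q = 0`:
#' `MSA = -intercept / slope`. Its 95% CI comes from the delta method for
#' a ratio of regression coefficients:
#' `var(MSA) = (1/slope^2) * (se_intercept^2 + MSA^2 * se_slope^2
#'  + 2 * MSA * cov_si)`.
#' A perfect fit (zero residual) yields a zero-width interval; a
#' non-positive slope is not projectable.
#'
#' @param fit A `loglinear_fit`.
#' @return An object of class `msa_estimate` with `msa`, `ci95`
#'   (`c(low, high)`), the originating `fit`, and the table metadata.
#' @export
#' @examples
#' f <- fit_loglinear_mortality(make_loglinear_q_table(gompertz_params(1e-4, 0.1)))
#' msa_from_fit(f)$msa        # -log(1e-4)/0.1 = 92.1034
msa_from_fit <- function(fit) {
  if (!inherits(fit, "loglinear_fit"))
    ll_abort("expected a loglinear_fit", "lifelimits_validation")
  if (fit$slope <= 0)
    ll_abort("slope must be positive to project to q = 1", "lifelimits_nonprojectable")
  msa <- -fit$intercept / fit$slope
  v <- (fit$se_intercept^2 + msa^2 * fit$se_slope^2 + 2 * msa * fit$cov_si) /
    fit$slope^2
  half <- stats::qnorm(0.975) * sqrt(max(v, 0))
  structure(list(population_id = fit$population_id,
                 index_year = fit$index_year,
                 table_type = fit$table_type,
                 msa = msa, ci95 = c(msa - half, msa + half), fit = fit),
            class = "msa_estimate")
}

#' @export
print.msa_estimate <- function(x, ...) {
  cat(sprintf("<msa_estimate> %s %s %s: MSA = %.2f y (95%% CI %.2f-%.2f), R2 = %.4f\n",
              x$population_id, x$table_type,
              ifelse(is.na(x$index_year), "", x$index_year),
              x$msa, x$ci95[1], x$ci95[2], x$fit$r2))
  invisible(x)
}

#' Estimate the maximum survivable age of one life table
#'
#' Convenience composition of [fit_loglinear_mortality()] and
#' [msa_from_fit()].
#'
#' @inheritParams fit_loglinear_mortality
#' @return An `msa_estimate`.
#' @export
estimate_msa <- function(lt, age_window = c(40, 95), zero_policy = "drop") {
  msa_from_fit(fit_loglinear_mortality(lt, age_window, zero_policy))
}

#' MSA estimates across a collection of life tables
#'
#' One estimate per population-year. Tables whose fit is not projectable
#' (non-positive slope) or has too few usable ages are recorded with a
#' `status` explaining why and an `NA` estimate — never silently dropped,
#' so a noisy series cannot fabricate a limit by attrition. The median
#' `r2` across successful fits is attached as attribute `median_r2`.
#'
#' @param tables List of [lifetable]s.
#' @inheritParams fit_loglinear_mortality
#' @return A tibble with columns `population_id`, `index_year`,
#'   `table_type`, `msa`, `ci_low`, `ci_high`, `slope`, `intercept`,
#'   `r2`, `n_ages`, `status`.
#' @export
#' @examples
#' s <- make_improving_series(gompertz_params(6e-5, 0.1), years = 1900:1905)
#' msa_series(s)$msa
msa_series <- function(tables, age_window = c(40, 95), zero_policy = "drop") {
  if (is_lifetable(tables)) tables <- list(tables)
  rows <- lapply(tables, function(lt) {
    base <- tibble::tibble(population_id = lt$population_id,
                           index_year = lt$index_year,
                           table_type = lt$table_type,
                           msa = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                           slope = NA_real_, intercept = NA_real_,
                           r2 = NA_real_, n_ages = NA_integer_,
                           status = NA_character_)
    tryCatch({
      est <- estimate_msa(lt, age_window, zero_policy)
      base$msa <- est$msa; base$ci_low <- est$ci95[1]; base$ci_high <- est$ci95[2]
      base$slope <- est$fit$slope; base$intercept <- est$fit$intercept
      base$r2 <- est$fit$r2; base$n_ages <- est$fit$n_ages
      base$status <- "ok"
      base
    },
    lifelimits_nonprojectable = function(e) { base$status <- paste("non_projectable:", conditionMessage(e)); base },
    lifelimits_insufficient_data = function(e) { base$status <- paste("insufficient_data:", conditionMessage(e)); base },
    lifelimits_zero_log = function(e) { base$status <- paste("zero_log:", conditionMessage(e)); base })
  })
  out <- do.call(rbind, rows)
  attr(out, "median_r2") <- stats::median(out$r2[out$status == "ok"], na.rm = TRUE)
  out
}

#' Compare observed ages at death with predicted survivable limits
#'
#' Matches each death record to an MSA estimate and counts how many
#' deaths fall within versus beyond the predicted limit, with the margin
#' `msa - age_at_death` per record. Two matching policies are offered
#' because record databases do not say which table "their" limit should
#' come from: `"cohort"` matches a record to the estimate whose
#' `index_year` is the birth year (death date minus age), `"period"` to
#' the estimate of the death year. Records with no (or no unambiguous)
#' matching estimate are listed as unmatched, never dropped.
#'
#' @param records Death-record tibble.
#' @param estimates An [msa_series()] tibble.
#' @param matching `"cohort"` or `"period"`.
#' @param by_country Additionally require `population_id == country`?
#' @return A list of class `msa_record_check`: `n_within`, `n_exceeding`,
#'   `margins` (per-record tibble) and `unmatched`.
#' @export
check_records_against_msa <- function(records, estimates,
                                      matching = c("cohort", "period"),
                                      by_country = FALSE) {
  records <- validate_death_records(records)
  matching <- match.arg(matching)
  est <- estimates[estimates$table_type == matching & !is.na(estimates$msa), ,
                   drop = FALSE]
  margins <- list(); unmatched <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    dec_year <- rec$death_year + (rec$death_month - 0.5) / 12
    target <- if (matching == "cohort") floor(dec_year - rec$age_at_death)
              else rec$death_year
    hit <- est[est$index_year == target, , drop = FALSE]
    if (by_country) hit <- hit[hit$population_id == rec$country, , drop = FALSE]
    if (nrow(hit) == 0) {
      unmatched[[length(unmatched) + 1]] <- tibble::tibble(
        record_id = rec$record_id,
        reason = sprintf("no %s estimate for year %d", matching, target))
    } else if (nrow(hit) > 1) {
      unmatched[[length(unmatched) + 1]] <- tibble::tibble(
        record_id = rec$record_id,
        reason = sprintf("%d candidate estimates for year %d; ambiguous",
                         nrow(hit), target))
    } else {
      margins[[length(margins) + 1]] <- tibble::tibble(
        record_id = rec$record_id, matched_year = target,
        msa = hit$msa, margin = hit$msa - rec$age_at_death,
        exceeds = rec$age_at_death > hit$msa)
    }
  }
  margins <- if (length(margins)) do.call(rbind, margins)
             else tibble::tibble(record_id = character(0), matched_year = integer(0),
                                 msa = numeric(0), margin = numeric(0),
                                 exceeds = logical(0))
  unmatched <- if (length(unmatched)) do.call(rbind, unmatched)
               else tibble::tibble(record_id = character(0), reason = character(0))
  structure(list(n_within = sum(!margins$exceeds),
                 n_exceeding = sum(margins$exceeds),
                 margins = margins, unmatched = unmatched),
            class = "msa_record_check")
}

#' @export
print.msa_record_check <- function(x, ...) {
  cat(sprintf("<msa_record_check> %d within limit, %d exceeding, %d unmatched\n",
              x$n_within, x$n_exceeding, nrow(x$unmatched)))
  invisible(x)
}
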