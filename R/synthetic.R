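#' Round a life table's survivors to integers
#'
#' Reproduces the published form of HMD survivorship: `lx` rounded to the
#' nearest integer on the 100,000 radix (ties away from zero by default,
#' which for positive counts means 0.5 rounds up). `qx` is left untouched
#' — rounding is a presentation artifact of `lx` only — and the input
#' table is not modified. Above roughly age 90 this rounding drives many
#' `lx` cells to exactly 0, the cells whose `log` downstream regressions
#' must not silently treat as `log(1)`.
#'
#' @param lt A [lifetable] with `precision = "exact"`.
#' @param ties `"away"` (default) or `"even"`.
#' @return A new [lifetable] with `precision = "integer_rounded"`.
#' @export
#' @examples
#' lt <- make_gompertz_lifetable(gompertz_params(3e-5, 0.1))
#' rounded <- apply_integer_rounding(lt)
#' max(abs(rounded$lx - lt$lx)) <= 0.5
apply_integer_rounding <- function(lt, ties = c("away", "even")) {
  ties <- match.arg(ties)
  validate_lifetable(lt)
  if (lt$precision == "integer_rounded") {
    ll_warn("table is already integer-rounded; returning it unchanged",
            "lifelimits_noop")
    return(lt)
  }
  out <- lt
  out$lx <- ifelse(is.na(lt$lx), NA_real_, round_ties(lt$lx, ties))
  out$radix <- round_ties(lt$radix, ties)
  out$precision <- "integer_rounded"
  validate_lifetable(out)
}

#' Cap a life table at a terminal open age interval
#'
#' Emulates the terminal age group of published life tables (HMD closes
#' at "110+"): ages above `cap` are merged into an open interval at `cap`
#' with `qx = 1`, keeping `lx` at the cap equal to the uncapped value, so
#' total deaths are conserved. The cap is an editorial convention, not a
#' biological limit; [age_of_greatest_gain()] on capped tables can never
#' return an age above it.
#'
#' @param lt A [lifetable].
#' @param cap Terminal age in years (default 110).
#' @return A capped [lifetable]; a no-op with a warning when `cap` is not
#'   below the table's maximum age.
#' @export
apply_age_cap <- function(lt, cap = 110) {
  validate_lifetable(lt)
  if (cap >= max(lt$ages)) {
    ll_warn(sprintf("cap %d is not below the table's maximum age %d; returning unchanged",
                    cap, max(lt$ages)), "lifelimits_noop")
    return(lt)
  }
  keep <- lt$ages <= cap
  out <- lt
  out$ages <- lt$ages[keep]
  out$qx <- lt$qx[keep]
  out$lx <- lt$lx[keep]
  out$qx[length(out$qx)] <- 1
  out$open_interval <- TRUE
  validate_lifetable(out)
}

#' Simulate an empirical life table from a finite cohort
#'
#' Draws `n` individual deaths from a ground-truth table's death
#' distribution (multinomial over per-age deaths `dx`, with the terminal
#' interval absorbing all remaining survivors) and rebuilds the observed
#' survivor counts and death probabilities. This is the finite-sample
#' object a real cohort life table estimates; it carries sampling noise
#' that the radix-scaled `qx` of the generator does not.
#'
#' @param lt Ground-truth [lifetable].
#' @param n Cohort size (default the table's radix).
#' @param seed Optional integer seed.
#' @return A [lifetable] with `radix = n`, observed integer `lx`, and
#'   empirical `qx = deaths/survivors` (`NA` where no survivors remain).
#' @export
simulate_empirical_lifetable <- function(lt, n = lt$radix, seed = NULL) {
  validate_lifetable(lt)
  dx <- lt_dx(lt)
  if (any(is.na(dx)))
    ll_abort("ground-truth table has missing lx; cannot simulate deaths",
             "lifelimits_parameter")
  deaths <- with_seed_(seed, as.numeric(stats::rmultinom(1, n, prob = dx / lt$radix)))
  surv <- n - cumsum(c(0, deaths[-length(deaths)]))
  qx <- ifelse(surv > 0, deaths / surv, NA_real_)
  lifetable(ages = lt$ages, qx = qx, lx = surv, radix = n,
            open_interval = lt$open_interval,
            population_id = paste0(lt$population_id, "_empirical"),
            index_year = lt$index_year, table_type = lt$table_type,
            sex = lt$sex, precision = "exact")
}

#' Generate a secularly improving series of life tables
#'
#' One period table per calendar year with baseline hazard
#' `a_y = a0 * (1 - annual_decline)^(y - y0)` and `b`, `c` fixed: the
#' simplest mechanism of secular mortality decline, which raises the
#' projected maximum survivable age linearly (MSA is `-log(a_y)/b` for
#' the exactly log-linear construction). Defaults emulate the 1900-1990
#' study window with a 1% annual decline in baseline hazard.
#'
#' @param params0 [gompertz_params] of the first calendar year.
#' @param annual_decline Proportional reduction in `a` per calendar year,
#'   in `[0, 1)` (default 0.01).
#' @param years Calendar years (default `1900:1990`).
#' @param max_age,radix Passed to the table builder.
#' @param q_model `"hazard"` (integrated-hazard `qx`, realistic, default)
#'   or `"loglinear"` (exactly log-linear `qx`).
#' @param population_id Population label carried by every table.
#' @return A list of period [lifetable]s ordered by year.
#' @export
#' @examples
#' s <- make_improving_series(gompertz_params(6e-5, 0.1), years = 1900:1905)
#' length(s)
make_improving_series <- function(params0, annual_decline = 0.01,
                                  years = 1900:1990, max_age = 110,
                                  radix = 1e5,
                                  q_model = c("hazard", "loglinear"),
                                  population_id = "synthetic_improving") {
  params0 <- as_gompertz_params(params0)
  q_model <- match.arg(q_model)
  if (!is.numeric(annual_decline) || annual_decline < 0 || annual_decline >= 1)
    ll_abort("annual_decline must be in [0, 1)", "lifelimits_parameter")
  y0 <- years[1]
  out <- lapply(years, function(y) {
    a_y <- params0$a * (1 - annual_decline)^(y - y0)
    p <- gompertz_params(a_y, params0$b, params0$c)
    if (q_model == "hazard")
      make_gompertz_lifetable(p, max_age = max_age, radix = radix,
                              population_id = population_id, index_year = y,
                              table_type = "period")
    else
      make_loglinear_q_table(p, max_age = max_age, radix = radix,
                             population_id = population_id, index_year = y)
  })
  names(out) <- as.character(years)
  out
}

#' Specify a multi-country supercentenarian record panel
#'
#' Describes the incidence process behind record databases like the IDL:
#' each country contributes validated deaths above a `threshold` age only
#' during its own coverage window of calendar years, at an expected
#' `annual_count` per covered year. Coverage windows that open and close
#' at different times are exactly the mechanism by which pooled maxima
#' can fall while every per-country trend is flat or rising.
#'
#' @param countries A list; each element a list with `country` (label),
#'   `params` ([gompertz_params] or a list with `a`, `b`, optional `c`),
#'   `coverage` (integer calendar years) and `annual_count` (expected
#'   validated deaths per covered year, `>= 0`).
#' @param threshold Minimum recorded age in years (default 110, the
#'   supercentenarian definition).
#' @param seed Optional default seed used by [simulate_record_panel()].
#' @return An object of class `panel_spec`.
#' @seealso [simulate_record_panel()], [read_panel_spec()]
#' @export
panel_spec <- function(countries, threshold = 110, seed = NULL) {
  if (!is.list(countries) || length(countries) == 0)
    ll_abort("'countries' must be a non-empty list", "lifelimits_parameter")
  countries <- lapply(countries, function(ct) {
    if (!all(c("country", "params", "coverage", "annual_count") %in% names(ct)))
      ll_abort("each country entry needs country, params, coverage, annual_count",
               "lifelimits_parameter")
    ct$params <- as_gompertz_params(ct$params)
    ct$coverage <- sort(unique(as.integer(ct$coverage)))
    if (length(ct$coverage) > 0 && any(!is.finite(ct$coverage)))
      ll_abort("coverage years must be finite", "lifelimits_parameter")
    if (!is.numeric(ct$annual_count) || ct$annual_count < 0)
      ll_abort("annual_count must be >= 0", "lifelimits_parameter")
    ct
  })
  structure(list(countries = countries, threshold = threshold, seed = seed),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> %d countries, threshold %g y\n",
              length(x$countries), x$threshold))
  for (ct in x$countries)
    cat(sprintf("  %s: %d covered years (%s..%s), ~%g deaths/y, a=%g b=%g c=%g\n",
                ct$country, length(ct$coverage),
                if (length(ct$coverage)) min(ct$coverage) else "-",
                if (length(ct$coverage)) max(ct$coverage) else "-",
                ct$annual_count, ct$params$a, ct$params$b, ct$params$c))
  invisible(x)
}

#' Serialize / deserialize a panel specification as YAML
#'
#' @param spec A [panel_spec].
#' @param path YAML file path.
#' @return `read_panel_spec` returns a [panel_spec]; `write_panel_spec`
#'   returns `path` invisibly.
#' @export
write_panel_spec <- function(spec, path) {
  stopifnot(inherits(spec, "panel_spec"))
  obj <- list(threshold = spec$threshold, seed = spec$seed,
              countries = lapply(spec$countries, function(ct)
                list(country = ct$country,
                     params = list(a = ct$params$a, b = ct$params$b, c = ct$params$c),
                     coverage = as.list(ct$coverage),
                     annual_count = ct$annual_count)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_panel_spec
#' @export
read_panel_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  panel_spec(countries = lapply(obj$countries, function(ct)
    list(country = ct$country, params = ct$params,
         coverage = unlist(ct$coverage), annual_count = ct$annual_count)),
    threshold = obj$threshold %||% 110, seed = obj$seed)
}

#' Simulate a supercentenarian record panel
#'
#' For each country and covered calendar year, draws a
#' `Poisson(annual_count)` number of validated deaths (or exactly
#' `annual_count`, rounded, under `count_model = "fixed"` for
#' variance-controlled experiments), with ages from the Gompertz
#' distribution conditional on exceeding the panel threshold and death
#' months uniform over the year. Fully reproducible under `seed`.
#'
#' @param spec A [panel_spec].
#' @param seed Integer seed (default the spec's own seed).
#' @param count_model `"poisson"` (default) or `"fixed"`.
#' @return A death-record tibble in the format of
#'   [read_death_records()]; empty (zero rows) when no coverage window
#'   produces a death.
#' @export
#' @examples
#' sp <- panel_spec(list(list(country = "FRA",
#'                            params = gompertz_params(3e-5, 0.1),
#'                            coverage = 1990:1992, annual_count = 3)))
#' simulate_record_panel(sp, seed = 1)
simulate_record_panel <- function(spec, seed = spec$seed,
                                  count_model = c("poisson", "fixed")) {
  stopifnot(inherits(spec, "panel_spec"))
  count_model <- match.arg(count_model)
  with_seed_(seed, {
    parts <- list()
    for (ct in spec$countries) {
      for (y in ct$coverage) {
        n <- if (count_model == "poisson") stats::rpois(1, ct$annual_count)
             else as.integer(round(ct$annual_count))
        if (n == 0) next
        ages <- sample_death_ages(ct$params, n, threshold = spec$threshold)
        months <- sample.int(12, n, replace = TRUE)
        parts[[length(parts) + 1]] <- tibble::tibble(
          record_id = sprintf("%s-%d-%03d", ct$country, y, seq_len(n)),
          age_at_death = ages,
          death_year = as.integer(y),
          death_month = as.integer(months),
          death_day = NA_integer_,
          country = ct$country,
          validation_status = "validated")
      }
    }
    if (length(parts) == 0) empty_death_records()
    else do.call(rbind, parts)
  })
}
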