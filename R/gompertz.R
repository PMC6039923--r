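#' Gompertz(-Makeham) mortality parameters
#'
#' The hazard is `h(x) = a * exp(b * x) + c`: a baseline hazard `a` at age
#' 0 that doubles every `log(2)/b` years, plus an optional age-independent
#' Makeham term `c`. Mortality doubling with age is the empirical
#' regularity that makes log-linear fits to adult death probabilities
#' work; `c` is provided only for robustness experiments.
#'
#' @param a Baseline hazard per year at age 0, `> 0`.
#' @param b Log-hazard slope per year, `> 0`.
#' @param c Makeham age-independent hazard per year, `>= 0` (default 0).
#' @return An object of class `gompertz_params`.
#' @export
#' @examples
#' gompertz_params(3e-5, 0.1)
gompertz_params <- function(a, b, c = 0) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    ll_abort("Gompertz 'a' must be a positive number", "lifelimits_parameter")
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0)
    ll_abort("Gompertz 'b' must be a positive number", "lifelimits_parameter")
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c < 0)
    ll_abort("Makeham 'c' must be a non-negative number", "lifelimits_parameter")
  structure(list(a = a, b = b, c = c), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("<gompertz_params> a = %g, b = %g (doubling %.2f y), c = %g\n",
              x$a, x$b, log(2) / x$b, x$c))
  invisible(x)
}

as_gompertz_params <- function(p) {
  if (inherits(p, "gompertz_params")) return(p)
  if (is.list(p) && all(c("a", "b") %in% names(p)))
    return(gompertz_params(p$a, p$b, p$c %||% 0))
  ll_abort("expected gompertz_params or a list with elements a, b", "lifelimits_parameter")
}

#' Gompertz-Makeham survival and hazard functions
#'
#' Closed forms: `h(x) = a e^{bx} + c` and
#' `S(x) = exp(-(a/b)(e^{bx} - 1) - c x)`.
#'
#' @param params A [gompertz_params].
#' @param x Ages in years.
#' @return Numeric vector of hazards / survival probabilities.
#' @export
gompertz_hazard <- function(params, x) {
  params <- as_gompertz_params(params)
  params$a * exp(params$b * x) + params$c
}

#' @rdname gompertz_hazard
#' @export
gompertz_survival <- function(params, x) {
  params <- as_gompertz_params(params)
  exp(-(params$a / params$b) * (exp(params$b * x) - 1) - params$c * x)
}

# integrated hazard over [x, x+1)
gompertz_H1 <- function(params, x) {
  (params$a / params$b) * (exp(params$b * (x + 1)) - exp(params$b * x)) +
    params$c
}

#' Build a life table whose log(qx) is exactly linear in age
#'
#' Sets `qx[x] = min(1, a * exp(b * x))`, so that below saturation
#' `log(qx)` lies exactly on the line `log(a) + b x`. This construction
#' makes the log-linear MSA estimator's exactness provable: the projected
#' age at which `q` reaches 1 is `-log(a)/b` in closed form. `lx` follows
#' by the survival recursion from the radix.
#'
#' @param params A [gompertz_params] with `c = 0` and `a < 1`.
#' @param max_age Oldest age row (default 110).
#' @param radix Survivors at age 0 (default 100,000).
#' @param population_id,index_year Metadata passed to [lifetable()].
#' @return A cohort [lifetable] with `precision = "exact"`.
#' @export
#' @examples
#' lt <- make_loglinear_q_table(gompertz_params(1e-4, 0.1))
#' lt$qx[1]                     # 1e-4
#' -log(1e-4) / 0.1             # age at which qx saturates at 1
make_loglinear_q_table <- function(params, max_age = 110, radix = 1e5,
                                   population_id = "synthetic_loglinear",
                                   index_year = NA_integer_) {
  params <- as_gompertz_params(params)
  if (params$c != 0)
    ll_abort("the exactly log-linear construction requires c = 0", "lifelimits_parameter")
  if (params$a >= 1)
    ll_abort("'a' must be < 1: q at age 0 would saturate", "lifelimits_parameter")
  ages <- 0:max_age
  qx <- pmin(1, params$a * exp(params$b * ages))
  lifetable(ages = ages, qx = qx, radix = radix,
            population_id = population_id, index_year = index_year,
            table_type = "cohort", precision = "exact")
}

#' Build a life table from the integrated Gompertz-Makeham hazard
#'
#' The realistic generator: `qx[x] = 1 - exp(-H(x))` where
#' `H(x) = (a/b)(e^{b(x+1)} - e^{bx}) + c` is the hazard integrated over
#' the single-year interval `[x, x+1)`. Unlike
#' [make_loglinear_q_table()], `log(qx)` here is only approximately linear
#' in age (the approximation the estimator exploits on real data), and
#' `qx` never reaches 1 at finite age.
#'
#' @inheritParams make_loglinear_q_table
#' @param params A [gompertz_params].
#' @param table_type `"cohort"` (default) or `"period"`.
#' @return A [lifetable] with `precision = "exact"` whose `lx[x]/radix`
#'   equals the closed-form survival `S(x)` to machine accuracy.
#' @export
#' @examples
#' p <- gompertz_params(3e-5, 0.1)
#' lt <- make_gompertz_lifetable(p, max_age = 100)
#' all.equal(lt$lx[81] / lt$radix, gompertz_survival(p, 80))
make_gompertz_lifetable <- function(params, max_age = 110, radix = 1e5,
                                    population_id = "synthetic_gompertz",
                                    index_year = NA_integer_,
                                    table_type = "cohort") {
  params <- as_gompertz_params(params)
  ages <- 0:max_age
  qx <- 1 - exp(-gompertz_H1(params, ages))
  lifetable(ages = ages, qx = qx, radix = radix,
            population_id = population_id, index_year = index_year,
            table_type = table_type, precision = "exact")
}

#' Sample ages at death from a Gompertz distribution
#'
#' Inverse-transform sampling from the continuous Gompertz age-at-death
#' distribution (`c = 0`): `x = (1/b) log(1 - (b/a) log U)` for
#' `U ~ Uniform(0,1)`. With a `threshold` t, draws come from the
#' distribution conditional on surviving past t,
#' `x = (1/b) log(e^{bt} - (b/a) log U)`, which is how supercentenarian
#' record databases arise (only deaths above 110 are registered).
#'
#' @param params A [gompertz_params] with `c = 0`.
#' @param n Number of draws.
#' @param threshold Minimum age in years, or `NULL` for unconditional
#'   draws.
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched. With `seed = NULL` the current stream is used.
#' @return Numeric vector of `n` fractional ages at death.
#' @export
#' @examples
#' a <- sample_death_ages(gompertz_params(3e-5, 0.1), 5, threshold = 110, seed = 1)
#' all(a > 110)
sample_death_ages <- function(params, n, threshold = NULL, seed = NULL) {
  params <- as_gompertz_params(params)
  if (params$c != 0)
    ll_abort("inverse-transform sampling requires c = 0", "lifelimits_parameter")
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n))
    ll_abort("'n' must be a non-negative integer", "lifelimits_parameter")
  if (n == 0) return(numeric(0))
  a <- params$a; b <- params$b
  with_seed_(seed, {
    u <- stats::runif(n)
    if (is.null(threshold)) {
      (1 / b) * log(1 - (b / a) * log(u))
    } else {
      (1 / b) * log(exp(b * threshold) - (b / a) * log(u))
    }
  })
}
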