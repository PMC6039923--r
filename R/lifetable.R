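#' Construct a life table
#'
#' A `lifetable` holds one population-year's age schedule of death
#' probabilities `qx` and survivors `lx` on a radix (100,000 by default,
#' the HMD convention). Ages are completed years; the interval `[x, x+1)`
#' is closed-open; the last age may be flagged as a terminal open interval
#' (the "110+" row of HMD tables), in which case its `qx` is 1.
#'
#' Tables carry a `precision` flag: `"exact"` tables satisfy the survival
#' recursion `lx[x+1] = lx[x] * (1 - qx[x])` to machine accuracy, while
#' `"integer_rounded"` tables hold `lx` rounded to the nearest integer, the
#' form in which HMD publishes them.
#'
#' @param ages Ascending integer ages in completed years.
#' @param qx Per-age probability of death, each in `[0, 1]`; `NA` allowed
#'   for missing cells.
#' @param lx Survivors at exact age. If `NULL`, built from `qx` by the
#'   survival recursion starting at `radix`.
#' @param radix Survivors at the first age (default 100,000).
#' @param open_interval Logical; is the last age a terminal open interval?
#'   If `NULL`, inferred as `qx` at the last age equalling 1.
#' @param population_id Label for the population.
#' @param index_year Calendar year (period tables) or birth year (cohort
#'   tables).
#' @param table_type `"period"` or `"cohort"`.
#' @param sex `"total"`, `"female"` or `"male"`.
#' @param precision `"exact"` or `"integer_rounded"`.
#' @return An object of class `lifetable`.
#' @seealso [make_gompertz_lifetable()], [read_hmd_lifetable()]
#' @export
#' @examples
#' lt <- lifetable(ages = 0:3, qx = c(0.01, 0.02, 0.5, 1),
#'                 index_year = 2000, table_type = "period")
#' lt$lx
lifetable <- function(ages, qx, lx = NULL, radix = 1e5, open_interval = NULL,
                      population_id = "synthetic", index_year = NA_integer_,
                      table_type = c("cohort", "period"),
                      sex = c("total", "female", "male"),
                      precision = c("exact", "integer_rounded")) {
  table_type <- match.arg(table_type)
  sex <- match.arg(sex)
  precision <- match.arg(precision)
  ages <- as.integer(ages)
  qx <- as.numeric(qx)
  if (is.null(lx)) {
    lx <- radix * cumprod(c(1, 1 - qx[-length(qx)]))
  }
  if (is.null(open_interval)) {
    qlast <- qx[length(qx)]
    open_interval <- !is.na(qlast) && qlast == 1
  }
  lt <- structure(
    list(population_id = as.character(population_id),
         index_year = as.integer(index_year),
         table_type = table_type,
         sex = sex,
         ages = ages,
         open_interval = isTRUE(open_interval),
         qx = qx,
         lx = as.numeric(lx),
         radix = as.numeric(radix),
         precision = precision),
    class = "lifetable")
  validate_lifetable(lt)
}

#' Validate a life table's invariants
#'
#' Checks that ages are strictly increasing, `qx` lies in `[0, 1]`, `lx`
#' starts at the radix and is non-increasing, a terminal open interval has
#' `qx = 1`, and (for `precision = "exact"`) that the survival recursion
#' holds to within `1e-12` of the radix per step.
#'
#' @param lt A `lifetable`.
#' @return `lt`, invisibly unchanged, or a validation error.
#' @export
validate_lifetable <- function(lt) {
  if (!inherits(lt, "lifetable"))
    ll_abort("not a lifetable object", "lifelimits_validation")
  n <- length(lt$ages)
  if (length(lt$qx) != n || length(lt$lx) != n)
    ll_abort("ages, qx and lx must have equal length", "lifelimits_validation")
  if (n == 0) ll_abort("empty life table", "lifelimits_validation")
  if (any(diff(lt$ages) <= 0))
    ll_abort(sprintf("ages not strictly increasing in table '%s' year %s",
                     lt$population_id, lt$index_year),
             "lifelimits_validation")
  bad_q <- !is.na(lt$qx) & (lt$qx < 0 | lt$qx > 1)
  if (any(bad_q))
    ll_abort("qx values outside [0, 1]", "lifelimits_validation")
  tol <- 1e-9 * lt$radix
  if (!is.na(lt$lx[1]) && abs(lt$lx[1] - lt$radix) > max(tol, 0.5 * (lt$precision == "integer_rounded")))
    ll_abort("lx at the first age must equal the radix", "lifelimits_validation")
  dl <- diff(lt$lx)
  if (any(!is.na(dl) & dl > tol))
    ll_abort("lx must be non-increasing in age", "lifelimits_validation")
  if (lt$open_interval) {
    qlast <- lt$qx[n]
    if (!is.na(qlast) && abs(qlast - 1) > 1e-12)
      ll_abort("terminal open interval must have qx = 1", "lifelimits_validation")
  }
  if (lt$precision == "exact" && n > 1) {
    pred <- lt$lx[-n] * (1 - lt$qx[-n])
    err <- abs(lt$lx[-1] - pred)
    ok <- is.na(err) | err <= 1e-12 * lt$radix
    if (!all(ok))
      ll_abort("exact table violates the survival recursion lx[x+1] = lx[x]*(1-qx[x])",
               "lifelimits_validation")
  }
  invisible(lt)
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> %s, %s %s table, year %s\n", x$population_id,
              x$sex, x$table_type,
              ifelse(is.na(x$index_year), "?", x$index_year)))
  cat(sprintf("  ages %d..%d%s, radix %s, precision %s\n",
              min(x$ages), max(x$ages), if (x$open_interval) "+" else "",
              format(x$radix, big.mark = ","), x$precision))
  invisible(x)
}

#' @export
as.data.frame.lifetable <- function(x, ...) {
  data.frame(age = x$ages, open = c(rep(FALSE, length(x$ages) - 1), x$open_interval),
             qx = x$qx, lx = x$lx)
}

#' @rdname lifetable
#' @param x Object to test.
#' @export
is_lifetable <- function(x) inherits(x, "lifetable")

# lx (or qx) at a single age; NA when absent
lx_at <- function(lt, age) lt$lx[match(age, lt$ages)]
qx_at <- function(lt, age) lt$qx[match(age, lt$ages)]

# deaths per age interval; the terminal interval absorbs all remaining
# survivors so that sum(dx) equals the radix
lt_dx <- function(lt) {
  n <- length(lt$lx)
  c(-diff(lt$lx), lt$lx[n])
}
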