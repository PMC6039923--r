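#' Quantify integer-rounding error in survivorship
#'
#' Pairs each exact table with its integer-rounded counterpart (aligned by
#' population and year) and summarises the per-age error
#' `rounded lx - exact lx` across population-years: the 2.5%, 50% and
#' 97.5% quantiles, plus the per-age fraction of tables whose rounded
#' `lx` is exactly 0. The error is defined on the `lx` count scale, not
#' the log scale, which both matches how the rounding is applied and
#' avoids `log(0)`. Against true exact references every error lies in
#' `[-0.5, 0.5]`; the zero fraction is the share of cells that a
#' log-transform downstream would have to drop (or mishandle).
#'
#' @param exact List of [lifetable]s with exact `lx`.
#' @param rounded Matching list with integer-rounded `lx`.
#' @return An object of class `rounding_report`: a per-age tibble
#'   (`age`, `q025`, `median`, `q975`, `zero_fraction`, `n`) plus the
#'   table count.
#' @export
#' @examples
#' s <- make_improving_series(gompertz_params(6e-5, 0.1), years = 1900:1909)
#' r <- lapply(s, apply_integer_rounding)
#' compute_rounding_errors(s, r)
compute_rounding_errors <- function(exact, rounded) {
  if (is_lifetable(exact)) exact <- list(exact)
  if (is_lifetable(rounded)) rounded <- list(rounded)
  key <- function(lt) paste(lt$population_id, lt$index_year, lt$sex, sep = "|")
  ke <- vapply(exact, key, character(1))
  kr <- vapply(rounded, key, character(1))
  if (anyDuplicated(ke) || anyDuplicated(kr))
    ll_abort("duplicate population-years in a collection", "lifelimits_validation")
  if (!setequal(ke, kr)) {
    miss <- c(setdiff(ke, kr), setdiff(kr, ke))
    ll_abort(sprintf("exact and rounded collections are misaligned: unmatched %s",
                     paste(miss, collapse = ", ")), "lifelimits_validation")
  }
  rounded <- rounded[match(ke, kr)]
  err_by_age <- list()
  zero_by_age <- list()
  for (i in seq_along(exact)) {
    e <- exact[[i]]; r <- rounded[[i]]
    if (!identical(e$ages, r$ages))
      ll_abort(sprintf("age grids differ for %s", ke[i]), "lifelimits_validation")
    for (j in seq_along(e$ages)) {
      ag <- as.character(e$ages[j])
      if (!is.na(e$lx[j]) && !is.na(r$lx[j])) {
        err_by_age[[ag]] <- c(err_by_age[[ag]], r$lx[j] - e$lx[j])
        zero_by_age[[ag]] <- c(zero_by_age[[ag]], r$lx[j] == 0)
      }
    }
  }
  ages <- sort(as.integer(names(err_by_age)))
  qs <- t(vapply(as.character(ages), function(ag)
    stats::quantile(err_by_age[[ag]], c(0.025, 0.5, 0.975), names = FALSE),
    numeric(3), USE.NAMES = FALSE))
  tab <- tibble::tibble(
    age = ages,
    q025 = qs[, 1], median = qs[, 2], q975 = qs[, 3],
    zero_fraction = vapply(as.character(ages),
                           function(ag) mean(zero_by_age[[ag]]), numeric(1),
                           USE.NAMES = FALSE),
    n = vapply(as.character(ages),
               function(ag) length(err_by_age[[ag]]), numeric(1),
               USE.NAMES = FALSE))
  structure(list(table = tab, n_tables = length(exact)),
            class = "rounding_report")
}

#' @export
print.rounding_report <- function(x, ...) {
  cat(sprintf("<rounding_report> %d population-years, ages %d..%d\n",
              x$n_tables, min(x$table$age), max(x$table$age)))
  zi <- x$table$zero_fraction > 0
  if (any(zi))
    cat(sprintf("  zero-rounded cells appear from age %d; zero fraction at top age: %.2f\n",
                min(x$table$age[zi]), x$table$zero_fraction[nrow(x$table)]))
  invisible(x)
}

#' @export
as.data.frame.rounding_report <- function(x, ...) as.data.frame(x$table)

#' Write a rounding report as CSV
#'
#' Columns: `age, q2.5, median, q97.5, zero_fraction, n`.
#'
#' @param report A `rounding_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rounding_report <- function(report, path) {
  stopifnot(inherits(report, "rounding_report"))
  df <- as.data.frame(report$table)
  names(df) <- c("age", "q2.5", "median", "q97.5", "zero_fraction", "n")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fraction of survivor cells rounded to zero above an age
#'
#' Across a collection of integer-rounded tables, the share of
#' `(table, age)` cells with `age > age_min` whose `lx` is exactly 0.
#' On published HMD data above age 90 this share exceeds one half — the
#' scale of the information loss that integer rounding inflicts on
#' late-life survival.
#'
#' @param tables List of [lifetable]s (meaningful for
#'   `precision = "integer_rounded"`).
#' @param age_min Cells strictly above this age are counted (default 90).
#' @return Proportion in `[0, 1]`.
#' @export
zero_rounded_fraction <- function(tables, age_min = 90) {
  if (is_lifetable(tables)) tables <- list(tables)
  zeros <- 0L; cells <- 0L
  for (lt in tables) {
    sel <- lt$ages > age_min & !is.na(lt$lx)
    cells <- cells + sum(sel)
    zeros <- zeros + sum(lt$lx[sel] == 0)
  }
  if (cells == 0)
    ll_abort(sprintf("no lx cells above age %g; fraction undefined", age_min),
             "lifelimits_undefined")
  zeros / cells
}

#' Log-transform survivor proportions under an explicit zero policy
#'
#' The operator at the heart of the log(0) critique. Survival proportions
#' rounded to zero have no finite logarithm; what a regression does with
#' them decides its result. Three policies:
#' \describe{
#'   \item{`drop`}{zeros (and missing values) are removed; the returned
#'     index map records which input positions were kept, so callers can
#'     report how many points each fit discarded.}
#'   \item{`as_one`}{`log(0)` is replaced by 0 — i.e. the zero is treated
#'     as if it were `log(1)`, survival of the whole cohort. This policy
#'     is retained only to reproduce the artifact it names; it silently
#'     converts the worst survival into the best.}
#'   \item{`fail`}{any zero raises an error.}
#' }
#'
#' @param values Survivor proportions in `[0, 1]`.
#' @param zero_policy `"drop"`, `"as_one"` or `"fail"`.
#' @return A list with `log` (transformed values) and `kept` (integer
#'   indices of the input positions retained).
#' @export
#' @examples
#' log_survival(c(0.5, 0), "drop")    # drops the zero, kept = 1
#' log_survival(c(0.5, 0), "as_one")  # log(0) -> 0: the artifact
log_survival <- function(values, zero_policy = c("drop", "as_one", "fail")) {
  zero_policy <- match.arg(zero_policy)
  if (any(!is.na(values) & (values < 0 | values > 1)))
    ll_abort("survivor proportions must lie in [0, 1]", "lifelimits_domain")
  is_zero <- !is.na(values) & values == 0
  if (zero_policy == "fail" && any(is_zero))
    ll_abort(sprintf("log(0) encountered at position(s) %s under policy 'fail'",
                     paste(which(is_zero), collapse = ", ")),
             "lifelimits_zero_log")
  if (zero_policy == "drop") {
    kept <- which(!is.na(values) & values > 0)
    return(list(log = log(values[kept]), kept = kept))
  }
  kept <- which(!is.na(values))
  lg <- log(values[kept])
  lg[values[kept] == 0] <- 0
  list(log = lg, kept = kept)
}
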