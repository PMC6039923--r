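#' Read HMD-style 1x1 life tables
#'
#' Parses the plain-text dialect used by the Human Mortality Database for
#' single-age, single-year life tables: a title line naming the population,
#' a blank line, a column-header line (`Year Age mx qx ax lx dx Lx Tx ex`)
#' and whitespace-delimited rows. The terminal row `110+` (any age with a
#' trailing `+`) is parsed as an open interval. Missing cells are written
#' as `"."` and are returned as `NA`, never as zero: silently turning a
#' missing survival count into 0 is precisely the failure mode that
#' corrupts downstream log-linear regressions.
#'
#' `lx` values that are whole numbers are stored with
#' `precision = "integer_rounded"` (HMD publishes rounded counts);
#' fractional `lx` columns (as written for exact synthetic tables) keep
#' `precision = "exact"`.
#'
#' @param path Path to the life-table text file.
#' @param table_type `"period"` or `"cohort"`; HMD files do not encode this
#'   distinction in the body, so the caller must say which it is.
#' @return A list of [lifetable] objects, one per calendar year, in file
#'   order.
#' @export
#' @examples
#' lt <- make_gompertz_lifetable(gompertz_params(3e-5, 0.1))
#' f <- tempfile(fileext = ".txt")
#' write_lifetable(list(lt), f)
#' read_hmd_lifetable(f, table_type = "cohort")[[1]]
read_hmd_lifetable <- function(path, table_type = c("period", "cohort")) {
  table_type <- match.arg(table_type)
  if (!file.exists(path))
    ll_abort(sprintf("life-table file not found: %s", path), "lifelimits_io")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3)
    ll_abort(sprintf("malformed header in %s: expected a title line, a blank line and a column header", path),
             "lifelimits_format")
  header_tokens <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  expected <- c("Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex")
  if (length(header_tokens) < 2 || !identical(header_tokens[1:2], c("Year", "Age")))
    ll_abort(sprintf("malformed header in %s: third line must start 'Year Age' (found '%s')",
                     path, lines[3]), "lifelimits_format")
  if (!identical(header_tokens, expected))
    ll_abort(sprintf("malformed header in %s: expected columns %s",
                     path, paste(expected, collapse = " ")), "lifelimits_format")
  population_id <- trimws(strsplit(lines[1], ",")[[1]][1])
  if (!nzchar(population_id)) population_id <- "unknown"
  sex <- "total"
  if (grepl("\\bfemale", lines[1], ignore.case = TRUE)) sex <- "female"
  else if (grepl("\\bmale", lines[1], ignore.case = TRUE)) sex <- "male"

  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(list())
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 10))
    ll_abort(sprintf("malformed row(s) in %s: expected 10 columns, found %d (first bad row %d)",
                     path, nf[which(nf != 10)[1]], which(nf != 10)[1]),
             "lifelimits_format")
  m <- do.call(rbind, fields)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  year <- as.integer(m[, 1])
  age_raw <- m[, 2]
  open <- grepl("\\+$", age_raw)
  age <- as.integer(sub("\\+$", "", age_raw))
  qx <- num(m[, 4])
  lx <- num(m[, 6])

  out <- list()
  for (y in unique(year)) {
    i <- which(year == y)
    if (any(diff(age[i]) <= 0))
      ll_abort(sprintf("non-monotone ages for year %d in %s", y, path),
               "lifelimits_validation")
    frac <- any(!is.na(lx[i]) & abs(lx[i] - round(lx[i])) > 1e-9)
    radix <- lx[i][1]
    if (is.na(radix)) radix <- 1e5
    out[[as.character(y)]] <- lifetable(
      ages = age[i], qx = qx[i], lx = lx[i], radix = radix,
      open_interval = any(open[i]),
      population_id = population_id, index_year = y,
      table_type = table_type, sex = sex,
      precision = if (frac) "exact" else "integer_rounded")
  }
  out
}

#' Write life tables in the HMD 1x1 text dialect
#'
#' Emits the same layout [read_hmd_lifetable()] accepts, so write-then-read
#' is an identity on the fields a [lifetable] carries. Integer-rounded `lx`
#' is written without a decimal point; exact `lx` keeps full precision (no
#' silent rounding). `dx` is derived from `lx` differences; the remaining
#' HMD columns (`mx`, `ax`, `Lx`, `Tx`, `ex`) are filled with standard
#' within-interval approximations (`ax = 0.5`) and are not read back.
#'
#' @param tables A list of [lifetable] objects sharing `population_id` and
#'   `table_type`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(tables, path) {
  if (is_lifetable(tables)) tables <- list(tables)
  if (length(tables) > 0) {
    types <- vapply(tables, function(t) t$table_type, character(1))
    if (length(unique(types)) > 1)
      ll_abort("cannot mix period and cohort tables in one file",
               "lifelimits_validation")
    pops <- vapply(tables, function(t) t$population_id, character(1))
    if (length(unique(pops)) > 1)
      ll_abort("cannot mix populations in one file", "lifelimits_validation")
    title <- sprintf("%s, Life tables (%s 1x1), %s", pops[1], types[1],
                     tables[[1]]$sex)
  } else {
    title <- "empty, Life tables (period 1x1), total"
  }
  fmt_num <- function(v, exact) {
    out <- rep(".", length(v))
    ok <- !is.na(v)
    out[ok] <- if (exact) sprintf("%.17g", v[ok]) else sprintf("%d", as.integer(round(v[ok])))
    out
  }
  lines <- c(title, "",
             paste("Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex",
                   sep = "  "))
  for (lt in tables) {
    n <- length(lt$ages)
    exact <- lt$precision == "exact"
    age_str <- as.character(lt$ages)
    if (lt$open_interval) age_str[n] <- paste0(age_str[n], "+")
    dx <- lt_dx(lt)
    ax <- rep(0.5, n)
    Lx <- lt$lx - (1 - ax) * dx
    Tx <- rev(cumsum(rev(Lx)))
    ex <- ifelse(lt$lx > 0, Tx / lt$lx, NA)
    mx <- ifelse(Lx > 0, dx / Lx, NA)
    qx_str <- ifelse(is.na(lt$qx), ".", sprintf("%.17g", lt$qx))
    rows <- paste(lt$index_year, age_str,
                  ifelse(is.na(mx), ".", sprintf("%.6g", mx)),
                  qx_str,
                  sprintf("%.2f", ax),
                  fmt_num(lt$lx, exact),
                  fmt_num(dx, exact),
                  ifelse(is.na(Lx), ".", sprintf("%.6g", Lx)),
                  ifelse(is.na(Tx), ".", sprintf("%.6g", Tx)),
                  ifelse(is.na(ex), ".", sprintf("%.2f", ex)),
                  sep = "  ")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a death-record table
#'
#' Reads a plain CSV in the style of the IDL/GRG supercentenarian lists,
#' with mandatory headers `id, age_years, death_date, country, status`.
#' Dates must be ISO (`YYYY-MM-DD` or `YYYY-MM`); they are stored as year,
#' month and (optional) day, since downstream filters need month
#' granularity. A row with an unparseable age or date is reported with its
#' row index and the whole file is rejected.
#'
#' @param path CSV path.
#' @return A [tibble::tibble] with columns `record_id`, `age_at_death`,
#'   `death_year`, `death_month`, `death_day`, `country`,
#'   `validation_status`.
#' @export
read_death_records <- function(path) {
  if (!file.exists(path))
    ll_abort(sprintf("death-record file not found: %s", path), "lifelimits_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "age_years", "death_date", "country", "status")
  if (!all(need %in% names(df)))
    ll_abort(sprintf("death-record CSV must have headers %s (found: %s)",
                     paste(need, collapse = ", "), paste(names(df), collapse = ", ")),
             "lifelimits_format")
  if (nrow(df) == 0) return(empty_death_records())
  age <- suppressWarnings(as.numeric(df$age_years))
  dm <- regmatches(df$death_date,
                   regexec("^(\\d{4})-(\\d{2})(?:-(\\d{2}))?$", df$death_date))
  year <- vapply(dm, function(m) if (length(m) >= 2) as.integer(m[2]) else NA_integer_, integer(1))
  month <- vapply(dm, function(m) if (length(m) >= 3) as.integer(m[3]) else NA_integer_, integer(1))
  day <- vapply(dm, function(m) if (length(m) >= 4 && nzchar(m[4])) as.integer(m[4]) else NA_integer_, integer(1))
  bad <- which(is.na(age) | age <= 0 | is.na(year) | is.na(month) |
                 month < 1 | month > 12)
  if (length(bad) > 0)
    ll_abort(sprintf("unparseable age or death date at row(s) %s of %s; file rejected",
                     paste(bad, collapse = ", "), path),
             "lifelimits_format")
  tibble::tibble(record_id = df$id, age_at_death = age,
                 death_year = year, death_month = month, death_day = day,
                 country = df$country, validation_status = df$status)
}

#' Write a death-record table
#'
#' Inverse of [read_death_records()]: emits `id, age_years, death_date,
#' country, status` with ISO dates (`YYYY-MM` when the day is unknown).
#'
#' @param records Death-record tibble as returned by [read_death_records()]
#'   or [simulate_record_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_death_records <- function(records, path) {
  records <- validate_death_records(records)
  date <- ifelse(is.na(records$death_day),
                 sprintf("%04d-%02d", records$death_year, records$death_month),
                 sprintf("%04d-%02d-%02d", records$death_year,
                         records$death_month, records$death_day))
  out <- data.frame(id = records$record_id,
                    age_years = sprintf("%.17g", records$age_at_death),
                    death_date = date,
                    country = records$country,
                    status = records$validation_status)
  if (nrow(out) == 0) out$death_date <- character(0)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_death_records <- function() {
  tibble::tibble(record_id = character(0), age_at_death = numeric(0),
                 death_year = integer(0), death_month = integer(0),
                 death_day = integer(0), country = character(0),
                 validation_status = character(0))
}

validate_death_records <- function(records) {
  need <- c("record_id", "age_at_death", "death_year", "death_month",
            "country", "validation_status")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    ll_abort(sprintf("death records must be a data frame with columns %s",
                     paste(need, collapse = ", ")), "lifelimits_validation")
  if (!"death_day" %in% names(records)) records$death_day <- NA_integer_
  records
}
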