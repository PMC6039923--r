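# Shared fixture builders: everything is generated in code at test time.

test_params <- function() gompertz_params(3e-5, 0.1)

# Panel emulating a record database whose large country stops being
# surveyed in 2003 while a small country continues to 2010, with
# identical underlying mortality.
test_panel_spec <- function(big_count = 40, small_count = 5) {
  p <- test_params()
  panel_spec(list(
    list(country = "BIG", params = p, coverage = 1980:2003,
         annual_count = big_count),
    list(country = "SMALL", params = p, coverage = 1980:2010,
         annual_count = small_count)),
    threshold = 110)
}

# A raw HMD-style file written by hand (not via write_lifetable), with a
# "110+" terminal row and "." missing cells, to pin the parsing contract.
write_raw_hmd_fixture <- function(path) {
  lines <- c(
    "Testland, Life tables (period 1x1), total",
    "",
    "Year  Age  mx  qx  ax  lx  dx  Lx  Tx  ex",
    "1900  0  0.01  0.0100  0.50  100000  1000  99500  5000000  50.0",
    "1900  1  0.002  0.0020  0.50  99000  198  98901  4900500  49.5",
    "1900  2  .  .  .  98802  .  .  .  .",
    "1900  110+  1.0  1.0  0.50  2  2  1  1  0.5",
    "1901  0  0.011  0.0110  0.50  100000  1100  99450  4990000  49.9",
    "1901  1  0.002  0.0021  0.50  98900  208  98796  4890550  49.4",
    "1901  2  0.001  0.0010  0.50  98692  99  98643  4791754  48.6",
    "1901  110+  1.0  1.0  0.50  3  3  2  2  0.5")
  writeLines(lines, path)
  path
}

# Small exact lifetable whose lx values exercise the rounding rule.
tie_table <- function() {
  # radix 100: lx = 100, 0.50, 0.49 -> tests ties-away and truncation
  lifetable(ages = 0:2, qx = c(0.995, 0.02, 1), radix = 100,
            index_year = 2000, table_type = "period")
}
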