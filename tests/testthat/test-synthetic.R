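test_that("exactly log-linear q tables evaluate and saturate in closed form", {
  lt <- make_loglinear_q_table(gompertz_params(1e-4, 0.1))
  expect_equal(lt$qx[1], 1e-4)
  expect_equal(lt$qx[11], 1e-4 * exp(1))
  # q reaches 1 exactly from the age ceiling(-log(a)/b) = 93 onward
  sat <- -log(1e-4) / 0.1
  expect_equal(min(lt$ages[lt$qx == 1]), ceiling(sat))
  expect_true(all(lt$qx[lt$ages < sat] < 1))
  # invariants across a parameter grid
  for (a in c(1e-5, 1e-4, 1e-3)) for (b in c(0.08, 0.12)) {
    t <- make_loglinear_q_table(gompertz_params(a, b), radix = 5e4)
    expect_equal(t$lx[1], 5e4)
    expect_true(all(diff(t$lx) <= 1e-9))
  }
  expect_error(make_loglinear_q_table(gompertz_params(1.5, 0.1)),
               class = "lifelimits_parameter")
})

test_that("hazard-integrated tables match the closed-form Gompertz survival", {
  p <- gompertz_params(3e-5, 0.1)
  lt <- make_gompertz_lifetable(p, max_age = 110)
  expect_equal(lt$lx[81] / lt$radix, gompertz_survival(p, 80),
               tolerance = 1e-12)
  expect_equal(lt$lx / lt$radix, gompertz_survival(p, lt$ages),
               tolerance = 1e-12)
  # 1 - exp(-H) <= H: qx never exceeds the integrated hazard
  H <- (p$a / p$b) * (exp(p$b * (lt$ages + 1)) - exp(p$b * lt$ages))
  expect_true(all(lt$qx <= H))
  # b -> 0 limit with c = 0: qx constant at 1 - exp(-a)
  small_b <- make_gompertz_lifetable(gompertz_params(0.01, 1e-9), max_age = 50)
  expect_equal(small_b$qx, rep(1 - exp(-0.01), 51), tolerance = 1e-6)
})

test_that("integer rounding follows ties-away, preserves the radix and stays within 0.5", {
  lt <- tie_table()                     # lx = 100, 0.50, 0.49
  r <- apply_integer_rounding(lt)
  expect_equal(r$lx, c(100, 1, 0))
  expect_equal(r$lx[1], 100)            # radix cell unchanged
  expect_equal(r$precision, "integer_rounded")
  expect_equal(lt$lx, c(100, 0.50, 0.49))  # input not modified
  expect_warning(apply_integer_rounding(r), class = "lifelimits_noop")
  # nearest-even alternative, on a table whose 0.5 is exactly representable
  half <- lifetable(ages = 0:2, qx = c(0.96875, 0.02, 1), radix = 16,
                    index_year = 2000, table_type = "period")
  expect_equal(half$lx, c(16, 0.5, 0.49))
  expect_equal(apply_integer_rounding(half, ties = "even")$lx, c(16, 0, 0))
  expect_equal(apply_integer_rounding(half, ties = "away")$lx, c(16, 1, 0))
  # property: |rounded - exact| <= 0.5 everywhere, qx untouched
  for (a in c(2e-5, 8e-5)) {
    e <- make_gompertz_lifetable(gompertz_params(a, 0.1))
    rr <- apply_integer_rounding(e)
    expect_true(all(abs(rr$lx - e$lx) <= 0.5))
    expect_identical(rr$qx, e$qx)
  }
})

test_that("age capping produces a terminal open interval and conserves deaths", {
  lt <- make_gompertz_lifetable(test_params(), max_age = 120)
  capped <- apply_age_cap(lt, cap = 110)
  expect_length(capped$ages, 111)
  expect_true(capped$open_interval)
  expect_equal(capped$qx[111], 1)
  expect_equal(capped$lx[111], lt$lx[match(110, lt$ages)])  # lx conserved at cap
  # accounting oracle: all radix deaths occur somewhere
  dx <- c(-diff(capped$lx), capped$lx[length(capped$lx)])
  expect_equal(sum(dx), capped$radix, tolerance = 1e-9)
  expect_warning(apply_age_cap(lt, cap = 120), class = "lifelimits_noop")
})

test_that("Gompertz death-age sampling honours truncation, seed and the mean oracle", {
  p <- test_params()
  above <- sample_death_ages(p, 500, threshold = 110, seed = 4)
  expect_true(all(above > 110))
  expect_identical(sample_death_ages(p, 100, seed = 9),
                   sample_death_ages(p, 100, seed = 9))
  # numerical-integration oracle for the unconditional mean age at death
  n <- 200000
  draws <- sample_death_ages(p, n, seed = 5)
  mu <- stats::integrate(function(x) gompertz_survival(p, x), 0, Inf)$value
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - mu), 3 * se)
  expect_error(sample_death_ages(gompertz_params(1e-5, 0.1, c = 1e-3), 10),
               class = "lifelimits_parameter")
})

test_that("record panels respect coverage windows, counts and seeds", {
  p <- test_params()
  none <- simulate_record_panel(
    panel_spec(list(list(country = "X", params = p, coverage = 2000,
                         annual_count = 0))), seed = 1)
  expect_equal(nrow(none), 0)
  two <- panel_spec(list(
    list(country = "A", params = p, coverage = 1990:1994, annual_count = 8),
    list(country = "B", params = p, coverage = 2000:2004, annual_count = 8)))
  rec <- simulate_record_panel(two, seed = 2)
  expect_setequal(unique(rec$death_year), c(1990:1994, 2000:2004))
  expect_true(all(rec$age_at_death > 110))
  expect_true(all(rec$death_month %in% 1:12))
  expect_identical(simulate_record_panel(two, seed = 3),
                   simulate_record_panel(two, seed = 3))
  # fixed-count variant for variance-controlled experiments
  fixed <- simulate_record_panel(two, seed = 2, count_model = "fixed")
  expect_equal(nrow(fixed), 8 * 10)
})

test_that("panel specs round-trip through YAML", {
  sp <- test_panel_spec()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_panel_spec(sp, f)
  back <- read_panel_spec(f)
  expect_equal(back$threshold, sp$threshold)
  expect_equal(length(back$countries), length(sp$countries))
  expect_equal(back$countries[[1]]$params$a, sp$countries[[1]]$params$a)
  expect_equal(back$countries[[2]]$coverage, sp$countries[[2]]$coverage)
  expect_identical(simulate_record_panel(back, seed = 5),
                   simulate_record_panel(sp, seed = 5))
})

test_that("secular improvement lowers hazard, raises survival, and is near log-linear", {
  p0 <- gompertz_params(6e-5, 0.1)
  flat <- make_improving_series(p0, annual_decline = 0, years = 1950:1955)
  for (t in flat[-1]) expect_equal(t$qx, flat[[1]]$qx)
  imp <- make_improving_series(p0, annual_decline = 0.01, years = 1900:1990)
  l100 <- vapply(imp, function(t) t$lx[match(100, t$ages)], numeric(1))
  expect_true(all(diff(l100) > 0))
  # oracle: recompute log survival at 100 from the closed form
  years <- 1900:1990
  a_y <- p0$a * 0.99^(years - 1900)
  oracle <- vapply(seq_along(years), function(i)
    log(gompertz_survival(gompertz_params(a_y[i], p0$b), 100)), numeric(1))
  expect_equal(unname(log(l100 / 1e5)), oracle, tolerance = 1e-9)
  # log lx is near-linear in year only while the cumulative decline in a is
  # modest (the b-dominated regime); over 1900-1945 the linear fit is tight
  fit <- linear_trend(annual_series(years[1:46], oracle[1:46]))
  expect_gt(fit$r^2, 0.99)
  # log(-log S), by contrast, is exactly linear in calendar year
  fit2 <- linear_trend(annual_series(years, log(-oracle)))
  expect_equal(fit2$mse, 0, tolerance = 1e-12)
  expect_equal(fit2$slope, log(0.99), tolerance = 1e-9)
})

test_that("empirical cohorts reproduce the ground truth at the radix scale", {
  lt <- make_loglinear_q_table(gompertz_params(1e-4, 0.1))
  emp <- simulate_empirical_lifetable(lt, n = 1e5, seed = 21)
  expect_equal(emp$radix, 1e5)
  expect_equal(emp$lx[1], 1e5)
  expect_true(all(diff(emp$lx) <= 0))
  expect_identical(simulate_empirical_lifetable(lt, 1e4, seed = 3)$lx,
                   simulate_empirical_lifetable(lt, 1e4, seed = 3)$lx)
  # observed qx is close to truth where cohorts are still large
  mid <- emp$ages >= 40 & emp$ages <= 70
  expect_equal(emp$qx[mid], lt$qx[mid], tolerance = 0.2)
})

test_that("the expected sample maximum is non-decreasing in sample size", {
  # common random numbers: the max over a nested subset can never exceed
  # the max over the full draw, so monotonicity holds replicate-by-replicate
  p <- test_params()
  reps <- 50
  m10 <- m100 <- m1000 <- numeric(reps)
  for (i in seq_len(reps)) {
    ages <- sample_death_ages(p, 1000, threshold = 110, seed = 600 + i)
    m10[i] <- max(ages[1:10]); m100[i] <- max(ages[1:100]); m1000[i] <- max(ages)
  }
  expect_true(all(m10 <= m100 & m100 <= m1000))
  expect_lte(mean(m10), mean(m100))
  expect_lte(mean(m100), mean(m1000))
})
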