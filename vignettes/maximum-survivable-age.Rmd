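---
title: "Estimating the maximum survivable age, and the data artifacts that mimic lifespan limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the maximum survivable age, and the data artifacts that mimic lifespan limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifelimits)
```

## The model

Adult human mortality rises close to exponentially with age: the
age-specific probability of death $q_x$ (the chance that someone alive at
exact age $x$ dies before $x+1$) approximately satisfies

$$\log q_x = \alpha + \beta x,$$

the discrete-age face of the Gompertz law $h(x) = a e^{bx}$. `lifelimits`
exploits this regularity for a deliberately simple projection: fit the
line by ordinary least squares over an adult age window and solve for the
age at which it reaches $\log q = 0$, i.e. $q = 1$,

$$\mathrm{MSA} = -\hat\alpha / \hat\beta.$$

This *maximum survivable age* is the age at which the fitted mortality
schedule leaves no room for survival — a conservative, population-level
upper bound on attainable lifespan, independent of how many people were
ever observed at extreme ages. It is conservative because it assumes no
late-life deceleration of mortality; any such deceleration (which we do
not model) would raise the bound. It is a population quantity: it says
nothing about individual variation in mortality acceleration.

Uncertainty comes from the delta method for a ratio of regression
coefficients:

$$\mathrm{var}(\mathrm{MSA}) \approx \frac{1}{\hat\beta^2}\left(
  \mathrm{se}_\alpha^2 + \mathrm{MSA}^2\,\mathrm{se}_\beta^2
  + 2\,\mathrm{MSA}\,\mathrm{cov}(\hat\alpha,\hat\beta)\right).$$

We chose the delta interval over prediction-band crossing because it is
the standard construction for coefficient ratios and its coverage is
directly measurable by simulation (below). On finite cohorts of $10^5$
individuals its measured coverage is close to, but slightly below, the
nominal 95% (about 91–92% in our replications): the OLS standard errors
assume homoskedastic residuals, while binomial noise in empirical $q_x$
grows with age. We report this rather than patch it, since the interval
is also exactly what a practitioner refitting published tables would
compute.

## Why the machinery around the estimator exists

Published life tables and longevity record databases carry three
editorial conventions that can each *manufacture* an apparent lifespan
limit when fed naively into regressions. The package treats each one as
a first-class, reproducible operator rather than a cautionary footnote.

**Integer rounding of survivorship.** HMD-style tables publish the
survivors $l_x$ of a hypothetical cohort of 100,000, rounded to whole
people. Where true survival falls below 1 in 200,000, the published
value is exactly 0. `apply_integer_rounding()` reproduces this (ties
away from zero by default; the convention is not documented by the
source, so nearest-even is available), and `compute_rounding_errors()` /
`zero_rounded_fraction()` quantify it. On a 1900-era synthetic series
the zero-rounded share above age 90 exceeds 90%.

**log(0) as log(1).** A regression on $\log(l_x/\text{radix})$ must do
*something* with those zeros. `log_survival()` makes the choice explicit
and mandatory: `drop` removes them (returning an index map so every fit
can report how many points it discarded), `fail` refuses, and `as_one`
replaces $\log 0$ with $0$ — re-coding complete extinction as complete
survival. `as_one` exists only because that substitution is the
documented failure mode we diagnose: on rounded tables it attenuates or
reverses the late-life survival gain rate that the exact data show
(`survival_change_rate()` under the two policies, the package's
`rounding_artifact` experiment).

**Terminal age caps.** Tables closed with a "110+" interval cannot, by
construction, locate any quantity above 110. `apply_age_cap()` emulates
the convention and `age_of_greatest_gain()` demonstrates the consequence:
on synthetic series whose gain-rate argmax lies above the cap, capped
tables report exactly 110.

**Pooled record panels with moving coverage.** Record databases are
incidence processes per country and year, with coverage windows that
open and close. Pooling countries while a large contributor exits
shrinks the annual sample, and the expected maximum of a smaller sample
is smaller — a decline in pooled maximum reported age at death (MRAD)
with no change in any country's mortality. `simulate_record_panel()`
generates such panels (Poisson counts per covered year, Gompertz ages
above a 110-year threshold via inverse-transform sampling), and
`annual_extreme()` + `segmented_trend()` show the pooled post-breakpoint
slope turning negative while every per-country slope stays centred on
zero.

## The synthetic-data generators and their defaults

Two $q_x$ constructions are provided on purpose:

- `make_loglinear_q_table()` sets $q_x = \min(1, a e^{bx})$, making
  $\log q_x$ *exactly* linear below saturation. On this input the
  estimator must recover $a$, $b$ and $\mathrm{MSA} = -\log(a)/b$ to
  machine precision, independent of the fitting window — exactness is
  provable, not approximate.
- `make_gompertz_lifetable()` integrates the hazard over each one-year
  interval, $q_x = 1 - e^{-H(x)}$ with
  $H(x) = \tfrac{a}{b}(e^{b(x+1)} - e^{bx}) + c$. Here $\log q_x$ is only
  approximately linear — the realistic situation the estimator faces on
  real tables ($R^2 > 0.999$ at the defaults, MSA within about one year
  of the hazard crossing $-\log(a)/b$).

Default parameter choices, made once:

- **Modern adult mortality** $a = 3\times10^{-5}$, $b = 0.1$ per year
  (mortality doubling time $\approx 6.9$ y, life expectancy $\approx 75$ y):
  used for record panels and the realism checks.
- **1900-era baseline for the secular-improvement series**
  $a_0 = 3\times10^{-4}$ ($e_0 \approx 52$ y), declining 1% per calendar
  year over 1900–1990 with $b$ fixed. The decline-in-$a$-only mechanism
  is the simplest one that raises MSA linearly (for the log-linear
  construction, $\mathrm{MSA}_y = -\log(a_y)/b$ grows by
  $-\log(0.99)/b \approx 0.1$ y per year). The 1900-era level matters for
  the rounding experiment: it is the regime in which $l_{105}$ on a
  100,000 radix genuinely rounds to zero for part of the century, which
  is the premise of the artifact. Replicated experiments draw
  $a_0 \sim U(2\times10^{-4}, 6\times10^{-4})$ and
  $b \sim U(0.09, 0.11)$, spanning $e_0 \approx 45$–57 y.
- **Record panel**: a large country contributing ~40 validated
  supercentenarian deaths per year, covered 1980–2003, and a small one
  contributing ~5, covered 1980–2010, with identical mortality — the
  qualitative structure of a database in which the majority contributors
  stop being surveyed after 2003. The breakpoint for segmented trends
  defaults to 1995.
- **Fitting window 40–95 years.** Below ~40, infant mortality and the
  early-adult excess bend $\log q_x$; above ~95, integer-rounded data
  degenerate. The window is configurable and always recorded in the fit.
  For *empirical* cohorts (finite-sample $q_x$ from simulated deaths) the
  recovery study uses 40–85: above ~85 a cohort of $10^5$ leaves a
  handful of survivors, empirical $q_x$ cells hit exactly 1 and are
  excluded by the $q \ge 1$ rule, which would otherwise select
  systematically low cells and bias the slope.
- **LOWESS**: span 0.67, 3 bisquare robustness iterations — standard
  choices for short annual series. The smoother is a degree-1 local
  regression with tricube weights over the span-nearest neighbours; a
  window that would fall below 2 points is widened to 2 with a warning.

What the generators deliberately do **not** emulate: frailty
heterogeneity, logistic/Kannisto late-life deceleration, cause-of-death
structure, migration, or HMD's internal smoothing of raw death counts
("exact" tables mean $q_x$-chained survivorship). Tests passing on this
synthetic ground truth therefore certify the estimator and the artifact
mechanisms, not the absence of those further complications in real data.

## Numerical and design choices

- **Ages** are completed years; intervals $[x, x+1)$ are closed-open; a
  terminal open interval carries $q_x = 1$. Only single-age, single-year
  (1×1) table layouts are read.
- **Missing cells** (`"."` in table files, empty in CSV) become `NA` and
  are excluded from fits — never coerced to 0, which is exactly the
  corruption the zero policies guard against.
- **$q_x$, not $m_x$,** is fitted: the projection is defined on the
  probability scale, and $q = 1$ is its natural ceiling. Ages with
  $q_x \ge 1$ are always excluded from fits; $q_x = 0$ follows the
  explicit zero policy.
- **Non-projectable fits** (slope $\le 0$) raise a typed condition;
  `msa_series()` records them as `NA` with a reason string so that a
  noisy collection cannot fabricate a limit by silently dropping
  failures.
- **Trend statistics**: unweighted OLS on (year, value); $p$-values from
  the classical two-sided $t$ test on the slope with $n-2$ df; no
  multiple-testing correction. `mse` is the mean squared residual
  (SSE/$n$). A zero-variance series reports $r = 0$, $p = 1$; an exactly
  collinear one reports $|r| = 1$, $p = 0$. Ties in ranked ages at death
  occupy consecutive ranks, stable by record id; the age of greatest gain
  breaks slope ties toward the older age, and a degenerate maximum (all
  slopes indistinguishable) warns.
- **Record-to-estimate matching**: a record database does not say which
  table "its" limit should come from, so `check_records_against_msa()`
  offers both birth-cohort matching (estimate year = death time minus
  age, floored) and period matching (estimate year = death year),
  optionally within country. Ambiguous or missing matches are reported
  unmatched, never guessed.
- **Seeding**: every stochastic operation takes an explicit seed and
  restores the caller's RNG stream; pipeline stages derive their seeds by
  a stable hash of (run seed, stage name), so adding a stage never
  perturbs another stage's draws.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run entirely on synthetic
data at sizes chosen to make Monte-Carlo error small relative to each
claim: 50 replicate cohorts of 100,000 simulated deaths for slope/MSA
recovery (the coverage proportion uses 200 replicates, so that its own
~2% Monte-Carlo error is small against the 85–99% acceptance band); 20
replicates each for the rounding and cap artifacts; 200 seeded panels
for the pooling artifact; 200 replicate years for the extreme-value
check. Because the true per-country post-breakpoint MRAD slope is
exactly zero under stationary mortality, its Monte-Carlo mean is tested
as "not below $-2\,\mathrm{SE}$" rather than literally $\ge 0$.

## Reproducing the external-data results

The headline numbers on real data — a maximum historic MSA above 125
years, median fit $R^2 \approx 0.99$ across thousands of population-
years, over half of published $l_x$ cells above age 90 rounded to zero,
and the sign reversal of the post-1995 MRAD trend once pooling and
outliers are handled — require the HMD, IDL and GRG databases, which are
user-supplied (no bundling or network access). With files in hand the
workflow is `read_hmd_lifetable()` / `read_death_records()` followed by
`msa_series()`, `zero_rounded_fraction()`, `annual_extreme()`,
`filter_records()` (month and id exclusions support the documented GRG
reconstruction and the leave-Calment-out check) and `segmented_trend()`;
the shipped test suite exercises this exact path on synthetic stand-ins.

## A worked example

```{r example}
# exact log-linear mortality: the projection is exact
lt <- make_loglinear_q_table(gompertz_params(1e-4, 0.1))
estimate_msa(lt)

# realistic hazard-integrated table
estimate_msa(make_gompertz_lifetable(gompertz_params(3e-5, 0.1)))

# the rounding artifact, end to end
series <- make_improving_series(gompertz_params(3e-4, 0.1), years = 1900:1990)
rounded <- lapply(series, apply_integer_rounding)
survival_change_rate(series, 105, "drop")$slope     # true gain rate
survival_change_rate(rounded, 105, "as_one")$slope  # the artifact
```

## Known limitations

- The projection inherits the log-linearity assumption wholesale; where
  real late-life mortality decelerates, the MSA is an underestimate of
  any true limit (and where early-adult mortality contaminates a
  too-wide window, the fit degrades visibly in $R^2$).
- The delta-method interval is mildly anticonservative on finite-cohort
  data (measured ~91% coverage at nominal 95%), for the
  heteroskedasticity reason above.
- Only 1×1 life-table layouts are parsed; abridged (5-year) tables are
  not supported.
- The breakpoint year of segmented trends is taken as given; no
  changepoint estimation is performed.
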