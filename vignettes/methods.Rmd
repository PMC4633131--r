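---
title: "Models and methods behind fooddemand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fooddemand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fooddemand)
```

`fooddemand` builds long-term national food demand scenarios from three
ingredients: a historical country-year panel of income and calorie
availability, a set of income-time regressions fitted to it, and
exogenous income/population projections that drive those regressions
forward. This vignette explains the models, the estimation and
calibration choices, what the synthetic-data generator does and does not
emulate, and the numerical decisions a user or reviewer may want to
audit.

## Data model and units

A panel row is one country-year: per-capita income `I` (US$2005
capita⁻¹ a⁻¹, market exchange rates), population `P` (capita), total
calorie demand `C_T` and animal-based calorie demand `C_L` (both kcal
capita⁻¹ d⁻¹). "Demand" here is food availability at the household
level — intake plus household waste — which is why high-income countries
can plausibly exceed 3500 kcal capita⁻¹ d⁻¹. Missing observations are
`NA`, never 0: a zero calorie value would be a (invalid) observation,
not the absence of one. Incomes on other currency bases are rebased
multiplicatively through a deflator table before fitting.

## Total calorie demand

The backbone is the power-law Engel curve `C_T = α·I^β`: demand rises
with income but under-proportionally (`0 < β < 1`). A single static
curve misses the persistent, income-unrelated drift in the data, so both
coefficients are allowed to move with calendar time, in two alternative
readings that bracket the plausible long run:

* `g_A(I,t) = exp(α₁ + α₂ t)·I^(β₁ + β₂ t)` — log-scale level and
  elasticity drift linearly forever.
* `g_B(I,t) = m_α(t)·I^(m_β(t))` with
  `m(t) = ω₁ + ω₂ (t−t₁)/(t−t₁+ω₃)`, `t₁ = 1960` — drift saturates, so
  late-century change is small.

`g_A` extrapolates the historical drift; `g_B` assumes it was largely a
transition. Both are consistent with the same history; a scenario
storyline picks one.

**Time convention.** Everywhere except inside `m(t)`, `t` is the raw
calendar year (2000, not 40). This matters for interpreting the
intercepts: `β₁` is the elasticity extrapolated to year 0, not to the
base year. The built-in reference coefficient sets reproduce their
published worked values (e.g. an elasticity of 0.101 in 1961) only
under this convention, which pins it down.

**Estimation.** `g_A` uses a transparent two-stage estimator: ordinary
least squares of `ln C_T` on `ln I` per year, then OLS lines through
the yearly `(α*, β)` values against the year. A single-stage
mixed-effects variant (`lme4`; year-level random intercept and random
`ln I` slope, with the same stage-2 lines through its year-specific
coefficients) is selectable via `fit_ga(panel, method = "mixed")`. The
two agree to well under 5% on clean panels; under heavy noise the
mixed model's shrinkage pulls yearly coefficients toward the line,
which is a feature for trend extraction but makes the two-stage fit
the more honest default for reporting uncertainty. The exact
random-effects structure of a mixed formulation is a genuinely open
choice; neither option is privileged beyond the default's transparency.

`g_B` runs a nonlinear least-squares power-law fit per year on the
untransformed calories (so high-calorie observations are not
down-weighted the way a log fit would), then fits `m(t)` to each
coefficient series.

## Animal-based calorie share

The share `C_LS = C_L/C_T` also gets two readings:

* `h_A = exp(κ₁ + κ₂ ln I + κ₃ t + κ₄ ln(I)·t)` — animal calories stay
  a normal good; the negative interaction `κ₄` bends the share down at
  high income late in the century.
* `h_B = (ρ₁ + ρ₂ t)·√I·exp(−(λ₁ + λ₂ t)·I)` — animal calories turn
  inferior at high income: an under-proportional square-root rise times
  an exponential decline, with a single interior maximum at
  `I* = 1/(2λ(t))` and a guaranteed non-negative share.

`h_A` is fitted by OLS on `ln C_LS` (zero shares are dropped, with the
count reported); `h_B` by nonlinear least squares on the untransformed
share (zero shares retained). The √I reading of the peaked form, with
raw US$ income and calendar-year time, is fixed by the same
worked-value reproduction argument as above: only that combination
reproduces the published share values at 60,000 US$ from the reference
coefficients. Note one acknowledged rough edge: the reference `h_B`
coefficients reproduce the published year-2100 value to printed
precision but give 0.26 rather than the published 0.28 at year 2000;
with four printed significant digits in the coefficients this cannot
be resolved further, and the package does not force it.

## Scenario construction and calibration

A storyline binds one total-calorie model and one share model
(`bind_storyline()`): materialistic storylines (A1, A2) take the
higher-consumption pair `g_A + h_A`, sustainability-oriented ones
(B1, B2) the saturating pair `g_B + h_B`; custom tags take any explicit
pair. Per-capita vegetal and animal demand are `g·(1−h)` and `g·h`, so
their sum is the total by construction; a share outside [0, 1] aborts
the projection rather than being clipped silently, because `1−h` would
go negative.

Calibration anchors projections in observed base-year diets. The
default `converge` mode applies

`conv(X_t, C₀, y_s, y_e) = ((t−y_s)·X_t + (y_e−t)·C₀)/(y_e−y_s)` for
`t ∈ [y_s, y_e]`, `X_t` beyond,

to the vegetal and animal series separately (defaults `y_s = 1990`,
`y_e = 2100`), so each country starts at its observed 1990 values and
reaches the regression surface by 2100 — a globalizing-diets
assumption. The alternative `preserve` mode multiplies each country's
projection by its base-year observed/projected ratio, keeping national
peculiarities forever; it yields visibly higher cross-country
dispersion, an ordering the test suite checks. Calibrating vegetal and
animal separately (rather than total and share) keeps the additive
identity exact at every stage.

Totals use `E = C · P · 4184 J kcal⁻¹ · 365 d a⁻¹`, reported in
10¹⁸ J a⁻¹. The thermochemical calorie and a 365-day year are defaults,
not physical necessities (published totals rarely state their
constants); both are arguments of `demand_totals()` and recorded in the
run manifest. Regional aggregation takes population-weighted means of
per-capita variables and sums of energy variables, so world totals are
invariant to the region partition.

## Validation battery

* `goodness_of_fit()` regresses observed on modelled values; slope,
  intercept, r², F.
* `mann_kendall()` tests for monotone trends: `S = Σ_{i<j} sign(v_j −
  v_i)`, exact permutation p-value for untied series with `n ≤ 10`
  (computed from the inversion-count distribution), tie-corrected
  normal approximation with continuity correction otherwise. The trend
  slope defaults to the median of consecutive differences divided by
  the step — the literal "differences between values and their
  successors" — with the all-pairs Sen median as an option. A partial
  (covariate-adjusted) variant conditions `S` on a supplied covariate's
  trend via the rank-based covariance of the two statistics; which
  covariate to condition on is left to the user, since no single choice
  is canonical for demand series.
* `bootstrap_sensitivity()` refits a model on random 67% subsamples of
  the complete observation pairs (without replacement, at the
  country-year level), dividing each coefficient by its full-data value
  and scoring the held-out third by observed-vs-modelled r². The
  reference configuration is 1000 replicates; the test suite and
  examples run 100, which already pins the ratio medians to well under
  1%. Replicate `r` draws with seed `seed + r`, so any replicate is
  individually reproducible.

## The synthetic-data generator

`synth_spec()`/`gen_panel()` produce panels with the statistical
structure the estimators assume, so the whole pipeline is testable
offline. What it emulates: 162 countries × 47 years (1961–2007, 7614
country-years); cross-country log-normal income levels (initial median
700 US$2005, log-sd 1.4 — about three orders of magnitude of spread, as
in the historical world panel) with per-country geometric growth rates
drawn once (2% ± 1.2% a⁻¹), so the country income ordering is
persistent; populations log-normal around 10⁷; calories generated from
a chosen total-calorie surface and share surface with multiplicative
log-normal noise (σ = 0.1 on both, matching the log-scale estimation of
the Engel curve); shares clipped at 1 with a reported count, and a
generating share ≥ 1 before noise refused as a domain error.
`gen_scenario()` continues the per-country trajectories from 1990 on a
5-year grid to 2100, with storyline-specific growth: globalized
storylines (A1, B1) pair faster income growth with decelerating
population that peaks before 2100; regionalized ones (A2, B2) keep
population growing at lower incomes, with 1990–2050 world growth
factors in the ranges typical of published storyline families.

What it does not emulate — and therefore what passing tests do not
show about real data: income shocks and business cycles (growth is
smooth), wars and famines, correlated (country-level) noise,
reporting-quality drift, the entry and exit of countries from the
record, and any supply-side constraint. Recovery results on synthetic
panels demonstrate estimator correctness, not that the historical
world identifies the models equally well.

## Numerical choices

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`,
  `ftol = 1e-10`, up to 1000 iterations), which also handles the
  zero-residual fits that arise on noiseless test fixtures.
* Yearly power-law starts: `α₀` at the geometric mean of the calorie
  values, `β₀ = 0.1`. Deterministic.
* The saturating trajectory `m(t)` is linear in `(ω₁, ω₂)` given `ω₃`,
  so candidate `ω₃` values on a fixed grid (including small negative
  values, which produce decreasing trajectories, with poles at
  `ω₃ = −(t−t₁)` excluded) are scored by their exact profiled
  least-squares solution; the best few seed the joint refinement. A
  series with negligible spread short-circuits to `ω₂ = 0` with a
  warning rather than an unidentified `ω₃`.
* `h_B` is initialized by profiling the level over a deterministic
  decay-rate grid (the level enters linearly given the decay), and the
  year is centered during optimization for conditioning; reported
  coefficients are uncentered back to calendar years.
* Parameter recovery on noisy panels is assessed on the evaluated
  coefficient *trajectories* over the observation window
  (`coef_trajectories()`): the calendar-year-origin intercepts are
  ~2000-year extrapolations, nearly collinear with their slopes, and
  not individually identifiable at realistic noise levels, while the
  trajectories they imply over 1961–2007 are. Noiseless recovery is
  asserted on the raw coefficients.
* Regional gap filling uses population-weighted donor means by default
  (consistent with every other regional aggregation in the package);
  an unweighted option exists because the choice is not forced by
  anything deeper than consistency.
* Stage outputs are written at 12 significant digits; parameter files
  at 17 (full double round trip).

The test suite runs the full battery at the study scale (162 × 47)
where it is cheap — single fits take well under a second — and smaller
panels (10–40 countries) where many pipeline stages are exercised
together; the bootstrap blocks use 100 replicates.

## Known limitations

Only income, population and time drive demand: prices, trade,
urbanization, demographics and supply constraints are out of scope by
design. The regressions are associative, not causal; the two share
families disagree exactly where data are thinnest (few historical
country-years above 40,000 US$), which is why both ship and the
storyline chooses. Calibration assumes either full convergence of
national diets by 2100 or full persistence — reality will sit between.
Trend tables for the historical world require the real FAOSTAT/WDI
extracts; with synthetic panels the package can only demonstrate the
machinery and its structural properties, not reproduce published
regional magnitudes.
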