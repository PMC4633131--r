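# Total-calorie Engel models: yearly power-law fits, the linear-time and
# saturating-time families, and their evaluation.

test_that("yearly power-law fit recovers exact data and handles edge cases", {
  set.seed(1)
  inc <- exp(runif(40, log(200), log(50000)))
  d <- food_panel(data.frame(country = sprintf("C%02d", 1:40), year = 1990L,
                             income = inc, population = 1e6,
                             total_cal = 900 * inc^0.10, animal_cal = 0))
  fit <- fit_yearly_power(d)
  expect_lt(rel_err(fit$alpha, 900), 1e-6)
  expect_lt(rel_err(fit$beta, 0.10), 1e-6)
  expect_equal(fit$n, 40L)

  flat <- d
  flat$total_cal <- 2500
  ffit <- fit_yearly_power(flat)
  expect_lt(abs(ffit$beta), 1e-8)
  expect_lt(rel_err(ffit$alpha, 2500), 1e-6)

  expect_error(fit_yearly_power(d[1:2, ]), ">= 3 complete")
  expect_error(fit_yearly_power(rbind(d, transform(d, year = 1991L))),
               "single year")
})

test_that("two-stage fit recovers the generating linear-time coefficients", {
  panel <- clean_panel_ga()
  fit <- fit_ga(panel)
  expect_true(all(rel_err(coef(fit), coef(ref$gA)) < 1e-3))
  d <- attr(fit, "diagnostics")
  expect_gt(d$r2_alpha_star, 0.999)
  expect_gt(d$r2_beta, 0.999)

  # elasticity at the start of the observation window rounds to 0.101
  expect_equal(round(fit$beta1 + fit$beta2 * 1961, 3), 0.101)

  single <- panel[panel$year == 1961, ]
  expect_error(fit_ga(single), "at least 2 years")
})

test_that("mixed-effects estimator agrees with the two-stage lines on a
           well-conditioned panel", {
  spec <- synth_spec(n_countries = 162,
                     total_model = ga_params(2.825, 2.131e-3, 0.30, -1e-4),
                     sigma_total = 0.01, sigma_share = 0, seed = 5)
  panel <- gen_panel(spec)
  two <- fit_ga(panel)
  mixed <- suppressWarnings(fit_ga(panel, method = "mixed"))
  expect_true(all(rel_err(coef(mixed), coef(two)) < 0.05))
})

test_that("linear-time model evaluation matches hand-computed values", {
  g <- ref$gA
  # printed-coefficient worked values at high income (coefficient
  # rounding allows 0.5%)
  expect_equal(eval_ga(g, 60000, 2000), 3587, tolerance = 0.005)
  expect_equal(eval_ga(g, 60000, 2100), 4289, tolerance = 0.005)
  # degenerate: no time dependence, unit income
  g0 <- ga_params(1.5, 0, 0.2, 0)
  expect_equal(eval_ga(g0, 1, 2050), exp(1.5))
  expect_error(eval_ga(g, -10, 2000), "income must be > 0")
})

test_that("saturating trajectory fit recovers generating curves", {
  yrs <- 1961:2007
  for (true in list(mm_params(933.9, 387.5, 9.775),
                    mm_params(8.941e-2, 8.445e-3, -0.7557))) {
    s <- data.frame(year = yrs, value = eval_mm(true, yrs))
    fit <- fit_michaelis_menten(s)
    expect_true(all(rel_err(coef(fit), coef(true)) < 1e-4))
  }

  const <- data.frame(year = yrs, value = 42)
  expect_warning(cfit <- fit_michaelis_menten(const), "flat series")
  expect_equal(cfit$omega1, 42)
  expect_equal(cfit$omega2, 0)

  expect_error(fit_michaelis_menten(data.frame(year = 1:3, value = 1:3)),
               ">= 4 points")
})

test_that("two-stage saturating-time fit recovers both trajectories", {
  panel <- clean_panel_gb()
  fit <- suppressWarnings(fit_gb(panel))
  expect_true(all(rel_err(coef(fit), coef(ref$gB)) < 1e-3))

  # yearly elasticities on the reference curves average near 9.9e-2
  expect_equal(mean(fit$yearly$beta), 9.88e-2, tolerance = 0.05)

  expect_error(fit_gb(panel[panel$year == 1961, ]), "at least 2 years")
})

test_that("saturating-time model evaluation matches printed worked values", {
  g <- ref$gB
  expect_equal(eval_gb(g, 60000, 2000), 3661, tolerance = 0.005)
  expect_equal(eval_gb(g, 60000, 2100), 3805, tolerance = 0.005)

  frozen <- gb_params(mm_params(1200, 0, 5), mm_params(0.1, 0, 5))
  expect_equal(eval_gb(frozen, 5000, 1970), eval_gb(frozen, 5000, 2100))
  expect_error(eval_gb(g, 0, 2000), "income must be > 0")
})

test_that("total-calorie models increase with income when elasticity is
           positive", {
  set.seed(99)
  inc <- sort(exp(runif(50, log(100), log(80000))))
  for (r in 1:20) {
    g <- ga_params(runif(1, 1, 4), runif(1, 0, 3e-3),
                   runif(1, 0.05, 0.5), -runif(1, 0, 2e-5))
    yr <- sample(1961:2100, 1)
    stopifnot(g$beta1 + g$beta2 * yr > 0)
    expect_true(all(diff(eval_ga(g, inc, yr)) > 0))
  }
  for (r in 1:20) {
    g <- gb_params(mm_params(runif(1, 500, 1500), runif(1, 0, 500),
                             runif(1, 1, 30)),
                   mm_params(runif(1, 0.05, 0.2), runif(1, 0, 0.05),
                             runif(1, 1, 30)))
    yr <- sample(1961:2100, 1)
    expect_true(all(diff(eval_gb(g, inc, yr)) > 0))
  }
})

test_that("noisy panels still identify the coefficient trajectories", {
  panel <- gen_panel(synth_spec(seed = 101))  # 162 x 47, sigma = 0.1
  fit <- fit_ga(panel)
  yrs <- 1961:2007
  err <- rel_err(coef_trajectories(fit, yrs), coef_trajectories(ref$gA, yrs))
  expect_lt(median(err), 0.05)
})

test_that("parameter files round-trip through the flat key-value format", {
  path <- withr::local_tempfile(fileext = ".txt")
  for (m in c("gA", "gB", "hA", "hB")) {
    write_params(ref[[m]], path)
    back <- read_params(path)
    expect_identical(coef(back), coef(ref[[m]]))
  }
  fit <- suppressWarnings(fit_gb(clean_panel_gb(n = 10)))
  write_params(fit, path)
  back <- read_params(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$m_alpha$t1, 1960)
})
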