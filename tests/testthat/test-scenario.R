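# Scenario engine: storyline binding, projection, convergence
# calibration, totals, regional aggregation.

ref_store <- list(gA = reference_params("gA"), gB = reference_params("gB"),
                  hA = reference_params("hA"), hB = reference_params("hB"))

test_that("storylines bind to their model pairs", {
  a1 <- bind_storyline("A1", ref_store)
  expect_identical(coef(a1$total), coef(ref_store$gA))
  expect_identical(coef(a1$share), coef(ref_store$hA))
  b2 <- bind_storyline("B2", ref_store)
  expect_identical(coef(b2$total), coef(ref_store$gB))
  expect_identical(coef(b2$share), coef(ref_store$hB))
  custom <- bind_storyline("frugal", total = ref_store$gB,
                           share = ref_store$hA)
  expect_identical(coef(custom$total), coef(ref_store$gB))
  expect_error(bind_storyline("unknown", ref_store[0]), "explicit")
})

test_that("per-capita projection splits the total exactly by the share", {
  spec <- synth_spec(n_countries = 12, seed = 3)
  scen <- gen_scenario(spec, "A1")
  b <- bind_storyline("A1", ref_store)
  pp <- project_percap(b, scen)
  # identity oracle: recompute the total model at every grid point
  expect_equal(pp$veg_percap + pp$animal_percap,
               eval_ga(ref_store$gA, pp$income, pp$year),
               tolerance = 1e-12)
  expect_equal(pp$veg_percap,
               pp$total_percap * (1 - pp$share), tolerance = 1e-12)
  # a degenerate zero-share model makes everything vegetal
  b0 <- bind_storyline("veg", total = ref_store$gA,
                       share = hb_params(0, 0, 1e-5, 0))
  pp0 <- project_percap(b0, scen)
  expect_equal(pp0$animal_percap, rep(0, nrow(pp0)))
  expect_equal(pp0$veg_percap, pp0$total_percap)
})

test_that("conv hits its boundary and midpoint identities", {
  expect_equal(conv(x = 3100, c0 = 2500, 1990, 2100, t = 1990), 2500)
  expect_equal(conv(x = 3100, c0 = 2500, 1990, 2100, t = 2100), 3100)
  expect_equal(conv(x = 3100, c0 = 2500, 1990, 2100, t = 2045),
               (3100 + 2500) / 2)
  expect_equal(conv(x = 3100, c0 = 2500, 1990, 2100, t = 2150), 3100)
  expect_error(conv(3100, 2500, 1990, 2100, t = 1980), "before the base")
  expect_error(conv(3100, 2500, 2100, 1990, t = 2000), "precede")
  # continuity at the convergence year
  eps <- 1e-9
  expect_equal(conv(3100, 2500, 1990, 2100, 2100 - eps),
               conv(3100, 2500, 1990, 2100, 2100 + eps), tolerance = 1e-6)
})

make_projection <- function(n = 15, seed = 3, storyline = "A1") {
  spec <- synth_spec(n_countries = n, sigma_total = 0.1, sigma_share = 0.1,
                     seed = seed)
  panel <- gen_panel(spec)
  scen <- gen_scenario(spec, storyline)
  pp <- project_percap(bind_storyline(storyline, ref_store), scen)
  base <- panel[panel$year == 1990, ]
  obs <- data.frame(country = base$country,
                    veg_cal = base$total_cal - base$animal_cal,
                    animal_cal = base$animal_cal)
  list(pp = pp, obs = obs)
}

test_that("converge calibration meets observations in the base year and
           preserve mode keeps relative deviations", {
  x <- make_projection()
  cal <- calibrate(x$pp, x$obs)
  b90 <- cal[cal$year == 1990, ]
  o <- x$obs[match(b90$country, x$obs$country), ]
  expect_equal(b90$veg_calib, o$veg_cal, tolerance = 1e-12)
  expect_equal(b90$animal_calib, o$animal_cal, tolerance = 1e-12)

  pres <- calibrate(x$pp, x$obs, mode = "preserve")
  # the observed/projected ratio of the base year persists at 2100
  p90 <- x$pp[x$pp$year == 1990, ]
  ratio90 <- o$veg_cal[match(p90$country, o$country)] / p90$veg_percap
  p2100 <- pres[pres$year == 2100, ]
  raw2100 <- x$pp[x$pp$year == 2100, ]
  expect_equal(p2100$veg_calib / raw2100$veg_percap,
               ratio90[match(p2100$country, p90$country)],
               tolerance = 1e-12)

  expect_error(calibrate(x$pp, x$obs[-1, ]), "missing base-year")
})

test_that("preserve mode keeps more cross-country dispersion than
           converge mode", {
  x <- make_projection(n = 40, seed = 12)
  conv_cal <- calibrate(x$pp, x$obs)
  pres_cal <- calibrate(x$pp, x$obs, mode = "preserve")
  sd_conv <- sd(conv_cal$total_calib[conv_cal$year == 2100])
  sd_pres <- sd(pres_cal$total_calib[pres_cal$year == 2100])
  expect_gt(sd_pres, sd_conv)
})

test_that("converge-mode dispersion shrinks toward the surface over time
           on a constant-income world", {
  yrs <- seq(1990, 2100, 5)
  n <- 25
  set.seed(4)
  tr <- expand.grid(country = sprintf("C%02d", 1:n), year = yrs)
  tr$income <- 5000
  tr$population <- 1e6
  scen <- scenario_input(tr, "flat")
  pp <- project_percap(bind_storyline("A1", ref_store), scen)
  # countries deviate +/- 20% from the surface in the base year
  dev <- runif(n, 0.8, 1.2)
  base <- pp[pp$year == 1990, ]
  obs <- data.frame(country = base$country,
                    veg_cal = base$veg_percap * dev,
                    animal_cal = base$animal_percap * dev)
  cal <- calibrate(pp, obs)
  disp <- vapply(split(cal$total_calib, cal$year), sd, numeric(1))
  # the surface itself is income-flat here, so dispersion decays
  # monotonically to zero at the convergence year
  expect_true(all(diff(disp) < 1e-12))
  expect_lt(disp[length(disp)], 1e-9)
})

test_that("total energy conversion applies the stated constants", {
  d <- data.frame(country = "AAA", year = 2000,
                  population = 1e9, veg_calib = 2000, animal_calib = 500)
  out <- demand_totals(d)
  expect_equal(out$energy_veg + out$energy_animal,
               2500 * 4184 * 365 * 1e9 / 1e18, tolerance = 1e-12)
  expect_equal(out$energy_veg + out$energy_animal, 3.8179, tolerance = 1e-4)

  zero <- demand_totals(transform(d, population = 0))
  expect_equal(zero$energy_veg, 0)
  expect_error(demand_totals(transform(d, veg_calib = -1)), "negative")

  # configurable constants change the result proportionally
  out2 <- demand_totals(d, kcal_to_joule = 4187, days_per_year = 365.25)
  expect_equal(out2$energy_veg / out$energy_veg,
               4187 * 365.25 / (4184 * 365), tolerance = 1e-12)
})

test_that("regional aggregation weights per-capita means by population and
           conserves world totals", {
  tab <- data.frame(country = c("AAA", "BBB"), year = 2000,
                    population = c(1e6, 3e6),
                    veg_calib = c(2000, 3000), animal_calib = c(500, 700))
  tab <- demand_totals(tab)
  map1 <- data.frame(country = c("AAA", "BBB"), region = "R1")
  reg <- aggregate_regions(tab, map1)
  expect_equal(reg$veg_calib, 2750)  # 1:3 weights on (2000, 3000)
  eq <- aggregate_regions(transform(tab, population = 2e6), map1)
  expect_equal(eq$veg_calib, 2500)

  # world totals invariant to the partition
  x <- make_projection(n = 20, seed = 9)
  cal <- demand_totals(calibrate(x$pp, x$obs))
  countries <- unique(cal$country)
  part_a <- data.frame(country = countries,
                       region = rep(c("R1", "R2"), length.out = 20))
  part_b <- data.frame(country = countries,
                       region = rep(c("R1", "R2", "R3", "R4"),
                                    length.out = 20))
  wa <- aggregate_regions(cal, part_a)
  wb <- aggregate_regions(cal, part_b)
  for (col in c("energy_veg", "energy_animal")) {
    expect_equal(sum(wa[[col]]), sum(wb[[col]]), tolerance = 1e-12)
    expect_equal(sum(wa[[col]]), sum(cal[[col]]), tolerance = 1e-12)
  }
  expect_error(aggregate_regions(cal, part_a[-1, ]), "without region")
})

test_that("vegetal + animal = total holds at every pipeline stage", {
  x <- make_projection(n = 10, seed = 21, storyline = "B2")
  pp <- x$pp
  expect_equal(pp$veg_percap + pp$animal_percap, pp$total_percap,
               tolerance = 1e-9)
  for (mode in c("converge", "preserve")) {
    cal <- calibrate(pp, x$obs, mode = mode)
    expect_equal(cal$veg_calib + cal$animal_calib, cal$total_calib,
                 tolerance = 1e-9)
  }
})

test_that("run_scenario produces per-stage outputs and a manifest, and is
           reproducible byte for byte", {
  spec <- synth_spec(n_countries = 10, seed = 3)
  panel <- gen_panel(spec)
  scen <- gen_scenario(spec, "B2")
  base <- panel[panel$year == 1990, ]
  obs <- data.frame(country = base$country,
                    veg_cal = base$total_cal - base$animal_cal,
                    animal_cal = base$animal_cal)
  rmap <- data.frame(country = unique(scen$trajectory$country),
                     region = rep(c("AFR", "SAS"), length.out = 10))
  run_once <- function(dir) {
    run_scenario(list(
      storyline = "B2",
      params = list(gB = reference_params("gB"),
                    hB = reference_params("hB")),
      scenario = scen, observed = obs, region_map = rmap,
      seed = 1, out_dir = dir))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_once(d1)
  run_once(d2)
  for (f in c("percap.csv", "calibrated.csv", "regional.csv",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(res$manifest$models$total, "gB")
  expect_equal(nrow(res$regional), 2 * 23)
})
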