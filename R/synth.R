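## Synthetic panels and scenario inputs with the statistical structure
## the demand regressions assume: log-normal cross-country income levels
## with persistent per-country geometric growth, calorie demand generated
## from a chosen total-calorie surface with multiplicative log-normal
## noise, and shares from a chosen share surface likewise.

#' Specify a synthetic historical panel
#'
#' The defaults emulate the historical estimation panel: 162 countries
#' over 1961-2007 (7614 country-years), incomes log-normally distributed
#' across countries (initial median about 700 US$2005 with a spread of
#' roughly three orders of magnitude, as in the historical cross-country
#' income distribution) with
#' per-country geometric growth rates drawn once (about 2% +/- 1.2% a^-1,
#' preserving the cross-country income ordering), populations log-normal
#' around 10 million, and calorie variables generated from the reference
#' linear-time total-calorie and log-linear share surfaces with 10%
#' multiplicative log-normal noise.
#'
#' @param n_countries number of countries (>= 2).
#' @param years integer year vector (>= 2 years).
#' @param total_model total-calorie parameter object (`gA` or `gB` family).
#' @param share_model share parameter object (`hA` or `hB` family).
#' @param sigma_total,sigma_share standard deviation of the log-normal
#'   multiplicative noise on total calories and on the share (>= 0).
#' @param income_log_mean,income_log_sd mean and sd of initial log income.
#' @param income_growth_mean,income_growth_sd per-country geometric income
#'   growth rate distribution (a^-1).
#' @param pop_log_mean,pop_log_sd mean and sd of initial log population.
#' @param pop_growth_mean,pop_growth_sd per-country population growth
#'   rate distribution (a^-1).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_countries = 162,
                       years = 1961:2007,
                       total_model = reference_params("gA"),
                       share_model = reference_params("hA"),
                       sigma_total = 0.1,
                       sigma_share = 0.1,
                       income_log_mean = log(700),
                       income_log_sd = 1.4,
                       income_growth_mean = 0.02,
                       income_growth_sd = 0.012,
                       pop_log_mean = log(1e7),
                       pop_log_sd = 1.5,
                       pop_growth_mean = 0.015,
                       pop_growth_sd = 0.008,
                       seed = 1L) {
  if (n_countries < 2L) stop_config("need at least 2 countries")
  if (length(years) < 2L) stop_config("need at least 2 years")
  if (sigma_total < 0 || sigma_share < 0) {
    stop_config("noise standard deviations must be >= 0")
  }
  structure(list(
    n_countries = n_countries, years = sort(unique(as.integer(years))),
    total_model = total_model, share_model = share_model,
    sigma_total = sigma_total, sigma_share = sigma_share,
    income_log_mean = income_log_mean, income_log_sd = income_log_sd,
    income_growth_mean = income_growth_mean,
    income_growth_sd = income_growth_sd,
    pop_log_mean = pop_log_mean, pop_log_sd = pop_log_sd,
    pop_growth_mean = pop_growth_mean, pop_growth_sd = pop_growth_sd,
    seed = as.integer(seed)), class = "synth_spec")
}

synth_countries <- function(spec) {
  sprintf("C%03d", seq_len(spec$n_countries))
}

## Per-country levels and growth rates; drawn once per spec so trajectories
## are persistent. Called under the spec's seed.
synth_country_draws <- function(spec) {
  n <- spec$n_countries
  list(
    income0 = exp(rnorm(n, spec$income_log_mean, spec$income_log_sd)),
    income_g = rnorm(n, spec$income_growth_mean, spec$income_growth_sd),
    pop0 = exp(rnorm(n, spec$pop_log_mean, spec$pop_log_sd)),
    pop_g = rnorm(n, spec$pop_growth_mean, spec$pop_growth_sd))
}

#' Generate a synthetic historical panel
#'
#' Incomes follow per-country geometric growth; total calories are the
#' total-calorie surface times `exp(N(0, sigma_total))`; the share is the
#' share surface times `exp(N(0, sigma_share))`, clipped at 1 (clip count
#' reported); animal calories are share times total. With zero noise the
#' panel lies exactly on the generating surfaces. A generating share at
#' or above 1 before noise is an error: such a parameter combination is
#' outside the models' domain.
#'
#' @param spec a [synth_spec()].
#' @return a [food_panel()] with attributes `synth_spec` and `n_clipped`.
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  draws <- synth_country_draws(spec)
  countries <- synth_countries(spec)
  t0 <- spec$years[1L]
  grid <- expand.grid(ci = seq_len(spec$n_countries), year = spec$years,
                      KEEP.OUT.ATTRS = FALSE)
  dt <- grid$year - t0
  income <- draws$income0[grid$ci] * exp(draws$income_g[grid$ci] * dt)
  population <- draws$pop0[grid$ci] * exp(draws$pop_g[grid$ci] * dt)

  total_clean <- eval_model(spec$total_model, income, grid$year)
  share_clean <- eval_model(spec$share_model, income, grid$year,
                            on_exceed = "clip")
  if (any(share_clean >= 1)) {
    stop_data(paste0("generating share model reaches 1 before noise; ",
                     "parameter combination outside the model domain"))
  }
  n <- nrow(grid)
  total_cal <- total_clean * exp(rnorm(n, 0, spec$sigma_total))
  share <- share_clean * exp(rnorm(n, 0, spec$sigma_share))
  n_clipped <- sum(share > 1)
  share <- pmin(share, 1)

  panel <- food_panel(data.frame(
    country = countries[grid$ci], year = grid$year,
    income = income, population = population,
    total_cal = total_cal, animal_cal = share * total_cal))
  attr(panel, "synth_spec") <- spec
  attr(panel, "n_clipped") <- n_clipped
  panel
}

storyline_growth <- function(storyline) {
  ## Income growth (mean a^-1, 1990 on) and population growth with a
  ## linear deceleration d (a^-2): P(t) = P_1990 exp(g dt - d dt^2 / 2),
  ## peaking at dt = g / d. Globalized storylines (A1, B1) pair fast
  ## income growth with decelerating population that peaks before 2100;
  ## regionalized ones (A2, B2) keep population growing at lower incomes.
  switch(storyline,
         A1 = list(income_g = 0.025, pop_g = 0.0144, pop_d = 2.0e-4),
         B1 = list(income_g = 0.020, pop_g = 0.0144, pop_d = 2.0e-4),
         B2 = list(income_g = 0.014, pop_g = 0.0111, pop_d = 5.0e-5),
         A2 = list(income_g = 0.012, pop_g = 0.0127, pop_d = 0),
         list(income_g = 0.018, pop_g = 0.0120, pop_d = 1.0e-4))
}

#' Generate a synthetic scenario input
#'
#' Income and population trajectories per country on a 1990-2100 grid in
#' 5-year steps, continuing the spec's per-country historical trajectories
#' from 1990 with storyline-specific mean growth. Globalized storylines
#' (A1, B1) decelerate population growth so that world population peaks
#' before 2100; A2 grows throughout; B2 decelerates mildly.
#'
#' @param spec a [synth_spec()].
#' @param storyline `"A1"`, `"A2"`, `"B1"`, `"B2"` or a custom tag
#'   (custom tags get middle-of-the-road growth).
#' @param start_year,end_year,step time grid (default 1990 to 2100 by 5).
#' @return a [scenario_input()].
#' @export
gen_scenario <- function(spec, storyline = "B2",
                         start_year = 1990, end_year = 2100, step = 5) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  draws <- synth_country_draws(spec)
  ## separate stream for scenario-specific growth jitter, still governed
  ## by the spec's seed
  set.seed(spec$seed + 1L)
  g <- storyline_growth(storyline)
  n <- spec$n_countries
  income_g <- rnorm(n, g$income_g, 0.005)
  pop_g <- rnorm(n, g$pop_g, 0.002)

  t0 <- spec$years[1L]
  years <- seq(start_year, end_year, by = step)
  grid <- expand.grid(ci = seq_len(n), year = years,
                      KEEP.OUT.ATTRS = FALSE)
  i1990 <- draws$income0[grid$ci] *
    exp(draws$income_g[grid$ci] * (start_year - t0))
  p1990 <- draws$pop0[grid$ci] *
    exp(draws$pop_g[grid$ci] * (start_year - t0))
  dt <- grid$year - start_year
  income <- i1990 * exp(income_g[grid$ci] * dt)
  population <- p1990 * exp(pop_g[grid$ci] * dt - g$pop_d * dt^2 / 2)

  scenario_input(data.frame(
    country = synth_countries(spec)[grid$ci], year = grid$year,
    income = income, population = population), storyline = storyline)
}

#' Blank random cells of a panel
#'
#' Each income/total/animal cell is blanked independently with the given
#' probability, to exercise gap filling; the intact panel is retained as
#' attribute `complete_panel` for oracle comparison.
#'
#' @param panel a [food_panel()].
#' @param fraction blanking probability in [0, 1).
#' @param seed integer seed.
#' @param cols columns eligible for blanking.
#' @return the panel with holes, and attributes `complete_panel` and
#'   `n_blanked`.
#' @export
inject_missingness <- function(panel, fraction, seed = 1L,
                               cols = c("income", "total_cal",
                                        "animal_cal")) {
  if (fraction < 0 || fraction >= 1) {
    stop_config("fraction must be in [0, 1)")
  }
  complete <- panel
  if (fraction > 0) {
    set.seed(seed)
    n_blanked <- 0L
    for (col in cols) {
      mask <- runif(nrow(panel)) < fraction
      if (col == "animal_cal") {
        panel[[col]][mask] <- NA_real_
      } else if (col == "total_cal") {
        ## removing the total also removes the animal value: a share
        ## without its denominator is not observable
        panel$total_cal[mask] <- NA_real_
        panel$animal_cal[mask] <- NA_real_
      } else {
        panel[[col]][mask] <- NA_real_
      }
      n_blanked <- n_blanked + sum(mask)
    }
    attr(panel, "n_blanked") <- n_blanked
  } else {
    attr(panel, "n_blanked") <- 0L
  }
  attr(panel, "complete_panel") <- complete
  panel
}
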