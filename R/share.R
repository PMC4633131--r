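## Animal-based calorie share: C_LS = C_L / C_T, with two alternative
## income-time regressions. h_A keeps livestock products a normal
## necessity good throughout (log-linear, income x time interaction);
## h_B lets them turn inferior at high incomes (sqrt rise x exponential
## decay, peaked in income).

#' Animal-based calorie share
#'
#' The ratio of animal-based to total calories, `C_LS = C_L / C_T`.
#'
#' @param animal_cal animal-based calories, kcal capita^-1 d^-1
#'   (0 <= animal_cal <= total_cal).
#' @param total_cal total calories, kcal capita^-1 d^-1 (> 0).
#' @return dimensionless fraction in \[0, 1\].
#' @export
animal_share <- function(animal_cal, total_cal) {
  if (any(total_cal <= 0, na.rm = TRUE)) {
    stop_data("total_cal must be > 0")
  }
  if (any(animal_cal < 0 | animal_cal > total_cal, na.rm = TRUE)) {
    stop_data("animal_cal must lie in [0, total_cal]")
  }
  animal_cal / total_cal
}

share_rows <- function(panel) {
  d <- panel[!is.na(panel$income) & !is.na(panel$total_cal) &
               !is.na(panel$animal_cal), , drop = FALSE]
  d <- d[d$income > 0 & d$total_cal > 0, , drop = FALSE]
  d$share <- animal_share(d$animal_cal, d$total_cal)
  d
}

clip_share <- function(x, on_exceed = c("clip", "error"), label) {
  on_exceed <- match.arg(on_exceed)
  out_of_range <- x < 0 | x > 1
  if (any(out_of_range)) {
    if (on_exceed == "error") {
      stop_data(sprintf("%s evaluated outside [0, 1] for %d value(s)",
                        label, sum(out_of_range)))
    }
    warning(sprintf("%s clipped to [0, 1] for %d value(s)",
                    label, sum(out_of_range)))
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

#' Fit the log-linear animal-share model
#'
#' Ordinary least squares of `ln C_LS` on `ln I`, calendar year `t` and
#' their interaction:
#' `ln C_LS = kappa1 + kappa2 ln I + kappa3 t + kappa4 ln(I) t`.
#' Rows with a zero share are dropped (log undefined); the count is kept
#' in the diagnostics.
#'
#' @param panel a [food_panel()] with at least 30 complete
#'   (income, total, animal) rows spanning at least 2 years.
#' @return object of class `c("ha_fit", "ha_params")`.
#' @export
fit_ha <- function(panel) {
  d <- share_rows(panel)
  n_zero <- sum(d$share == 0)
  d <- d[d$share > 0, , drop = FALSE]
  if (nrow(d) < 30L) {
    stop_data(sprintf("need >= 30 usable (income, share, year) rows, got %d",
                      nrow(d)))
  }
  if (length(unique(d$year)) < 2L) {
    stop_data("all observations in a single year: time terms not identifiable")
  }
  fit <- lm(log(share) ~ log(income) * year, data = d)
  cc <- coef(fit)
  if (anyNA(cc)) stop_numeric("collinear design in h_A regression")
  out <- ha_params(kappa1 = unname(cc["(Intercept)"]),
                   kappa2 = unname(cc["log(income)"]),
                   kappa3 = unname(cc["year"]),
                   kappa4 = unname(cc["log(income):year"]))
  attr(out, "diagnostics") <- list(
    r_squared = suppressWarnings(summary(fit))$r.squared, n_obs = nrow(d),
    n_zero_dropped = n_zero)
  class(out) <- c("ha_fit", class(out))
  out
}

#' Evaluate the log-linear animal-share model
#'
#' @param params [ha_params()] or a [fit_ha()] result.
#' @param income per-capita income (> 0), US$2005 capita^-1 a^-1.
#' @param year calendar year.
#' @param on_exceed `"clip"` (default; clip to \[0, 1\] with a warning) or
#'   `"error"` when the evaluated share leaves \[0, 1\].
#' @return share fraction in \[0, 1\].
#' @export
eval_ha <- function(params, income, year, on_exceed = c("clip", "error")) {
  if (any(income <= 0)) stop_data("income must be > 0")
  raw <- exp(params$kappa1 + params$kappa2 * log(income) +
               params$kappa3 * year + params$kappa4 * log(income) * year)
  clip_share(raw, on_exceed, "h_A share")
}

## Profile initialization for h_B: for a trial decay rate lambda the level
## rho enters linearly, so rho-hat(lambda) and the profiled SSE are closed
## form. A coarse deterministic lambda grid picks the start for the joint
## Levenberg-Marquardt refinement.
hb_start <- function(d, t_center) {
  lambdas <- c(0, 10^seq(-8, -3, length.out = 40))
  sse <- vapply(lambdas, function(l) {
    u <- sqrt(d$income) * exp(-l * d$income)
    rho <- sum(d$share * u) / sum(u^2)
    sum((d$share - rho * u)^2)
  }, numeric(1L))
  l0 <- lambdas[which.min(sse)]
  u <- sqrt(d$income) * exp(-l0 * d$income)
  list(r1 = sum(d$share * u) / sum(u^2), r2 = 0, l1 = l0, l2 = 0)
}

#' Fit the peaked animal-share model
#'
#' Nonlinear least squares on the untransformed share for
#' `C_LS = (rho1 + rho2 t) sqrt(I) exp(-(lambda1 + lambda2 t) I)`.
#' Internally the year is centered for conditioning (the reported
#' coefficients are on the calendar-year scale). Initialization profiles
#' the level coefficient over a deterministic decay-rate grid, then the
#' four coefficients are refined jointly. Zero shares are retained.
#'
#' @param panel a [food_panel()] with at least 30 complete rows spanning
#'   at least 2 years.
#' @return object of class `c("hb_fit", "hb_params")`.
#' @export
fit_hb <- function(panel) {
  d <- share_rows(panel)
  if (nrow(d) < 30L) {
    stop_data(sprintf("need >= 30 usable (income, share, year) rows, got %d",
                      nrow(d)))
  }
  if (length(unique(d$year)) < 2L) {
    stop_data("all observations in a single year: time terms not identifiable")
  }
  if (all(d$share <= 0) || sd(d$share) == 0) {
    stop_data("degenerate response: shares carry no variation")
  }
  t_center <- round(mean(d$year))
  d$tc <- d$year - t_center
  start <- hb_start(d, t_center)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      share ~ (a + b * tc) * sqrt(income) * exp(-(p + q * tc) * income),
      data = d,
      start = list(a = start$r1, b = start$r2, p = start$l1, q = start$l2),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12)),
    error = function(e) {
      stop_numeric(paste0("h_B fit did not converge: ", conditionMessage(e)))
    })
  cc <- coef(fit)
  ## uncenter: rho(t) = a + b (t - tc) = (a - b tc) + b t, same for lambda
  out <- hb_params(rho1 = unname(cc["a"] - cc["b"] * t_center),
                   rho2 = unname(cc["b"]),
                   lambda1 = unname(cc["p"] - cc["q"] * t_center),
                   lambda2 = unname(cc["q"]))
  attr(out, "diagnostics") <- list(
    rse = sqrt(sum(resid(fit)^2) / max(1L, nrow(d) - 4L)), n_obs = nrow(d))
  class(out) <- c("hb_fit", class(out))
  out
}

#' Evaluate the peaked animal-share model
#'
#' The share `(rho1 + rho2 t) sqrt(I) exp(-(lambda1 + lambda2 t) I)` has a
#' single interior maximum in income at `I* = 1 / (2 lambda(t))`. A
#' negative evaluated `rho(t)` or `lambda(t)` is a domain error (the share
#' would go negative or unbounded).
#'
#' @inheritParams eval_ha
#' @param params [hb_params()] or a [fit_hb()] result.
#' @return share fraction in \[0, 1\].
#' @export
eval_hb <- function(params, income, year, on_exceed = c("clip", "error")) {
  if (any(income <= 0)) stop_data("income must be > 0")
  rho <- params$rho1 + params$rho2 * year
  lambda <- params$lambda1 + params$lambda2 * year
  if (any(rho < 0)) stop_data("rho(t) < 0 in the evaluation range")
  if (any(lambda < 0)) stop_data("lambda(t) < 0 in the evaluation range")
  clip_share(rho * sqrt(income) * exp(-lambda * income), on_exceed,
             "h_B share")
}
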