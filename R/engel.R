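## Total calorie demand: the power-law Engel curve C_T = alpha * I^beta
## with two alternative time dependences of its coefficients.
##
## g_A: ln C_T regressed on ln I with yearly coefficients, whose time
##      paths are straight lines in calendar year (two-stage estimator;
##      a mixed-effects variant with year-level random intercept and
##      slope is available).
## g_B: yearly nonlinear power-law fits on untransformed calories, whose
##      coefficient time series are then fitted with saturating
##      Michaelis-Menten-type trajectories (base year 1960).

complete_total_rows <- function(panel) {
  panel[!is.na(panel$income) & !is.na(panel$total_cal), , drop = FALSE]
}

#' Fit the power-law Engel curve for a single year
#'
#' Nonlinear least squares for `C_T = alpha * I^beta`, minimizing
#' untransformed residuals (Levenberg-Marquardt). Deterministic starts:
#' `alpha` at the geometric mean of the calorie values, `beta = 0.1`.
#'
#' @param panel a [food_panel()] (or data.frame) holding observations of a
#'   single year; rows with missing income or total calories are dropped.
#' @return list of class `yearly_power_fit` with `year`, `alpha`, `beta`,
#'   residual standard error `rse` and `n`.
#' @export
fit_yearly_power <- function(panel) {
  d <- complete_total_rows(panel)
  years <- unique(d$year)
  if (length(years) > 1L) {
    stop_data("fit_yearly_power expects data from a single year")
  }
  if (nrow(d) < 3L) {
    stop_data(sprintf("need >= 3 complete (income, total_cal) pairs, got %d",
                      nrow(d)))
  }
  start <- list(alpha = exp(mean(log(d$total_cal))), beta = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(total_cal ~ alpha * income^beta, data = d,
                      start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-10)),
    error = function(e) {
      stop_numeric(paste0("yearly power-law fit failed for year ", years,
                          ": ", conditionMessage(e)))
    })
  cc <- coef(fit)
  structure(list(year = years, alpha = unname(cc["alpha"]),
                 beta = unname(cc["beta"]),
                 rse = sqrt(sum(resid(fit)^2) / max(1L, nrow(d) - 2L)),
                 n = nrow(d)),
            class = "yearly_power_fit")
}

stage2_line <- function(value, year) {
  fit <- lm(value ~ year)
  list(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]),
       r_squared = suppressWarnings(summary(fit))$r.squared)
}

#' Fit the linear-time total-calorie model
#'
#' Two-stage estimator for `g_A(I, t) = exp(alpha1 + alpha2 t) *
#' I^(beta1 + beta2 t)`: per-year ordinary least squares of `ln C_T` on
#' `ln I` gives yearly `(alpha*, beta)` values, then ordinary
#' least-squares lines of those values against calendar year give the
#' four coefficients. With `method = "mixed"`, the yearly coefficients
#' come instead from a single mixed-effects model with a year-level
#' random intercept and random `ln I` slope (lme4), and the same stage-2
#' lines are fitted to its year-specific coefficients.
#'
#' @param panel a [food_panel()].
#' @param method `"two-stage"` (default) or `"mixed"`.
#' @return object of class `c("ga_fit", "ga_params")`; usable directly by
#'   [eval_ga()]. Carries the per-year coefficient table (`$yearly`) and
#'   stage-2 `r^2` values as the `diagnostics` attribute.
#' @export
fit_ga <- function(panel, method = c("two-stage", "mixed")) {
  method <- match.arg(method)
  d <- complete_total_rows(panel)
  d <- d[d$income > 0 & d$total_cal > 0, , drop = FALSE]
  counts <- table(d$year)
  usable <- as.integer(names(counts)[counts >= 3L])
  skipped <- setdiff(unique(d$year), usable)
  if (length(skipped) > 0L) {
    warning("years with fewer than 3 complete pairs excluded: ",
            paste(skipped, collapse = ", "))
  }
  d <- d[d$year %in% usable, , drop = FALSE]
  if (length(usable) < 2L) {
    stop_data("need at least 2 years with >= 3 complete pairs each")
  }

  if (method == "two-stage") {
    yearly <- lapply(sort(usable), function(y) {
      dy <- d[d$year == y, , drop = FALSE]
      fit <- tryCatch(lm(log(total_cal) ~ log(income), data = dy),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(coef(fit))) {
        warning("stage-1 regression failed for year ", y, "; excluded")
        return(NULL)
      }
      data.frame(year = y, alpha_star = unname(coef(fit)[1L]),
                 beta = unname(coef(fit)[2L]), n = nrow(dy))
    })
    yearly <- do.call(rbind, yearly)
  } else {
    d$lC <- log(d$total_cal)
    d$lI <- log(d$income)
    mm <- lme4::lmer(lC ~ lI + (1 + lI | year), data = d,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
    cc <- coef(mm)$year
    yearly <- data.frame(year = as.integer(rownames(cc)),
                         alpha_star = cc[["(Intercept)"]],
                         beta = cc[["lI"]],
                         n = as.integer(table(d$year)[rownames(cc)]))
  }
  if (is.null(yearly) || nrow(yearly) < 2L) {
    stop_data("fewer than 2 years survived stage 1")
  }

  la <- stage2_line(yearly$alpha_star, yearly$year)
  lb <- stage2_line(yearly$beta, yearly$year)
  out <- ga_params(alpha1 = la$intercept, alpha2 = la$slope,
                   beta1 = lb$intercept, beta2 = lb$slope,
                   year_range = range(yearly$year))
  out$yearly <- yearly
  attr(out, "diagnostics") <- list(
    r2_alpha_star = la$r_squared, r2_beta = lb$r_squared,
    n_years = nrow(yearly), n_obs = nrow(d), method = method)
  class(out) <- c("ga_fit", class(out))
  out
}

#' Evaluate the linear-time total-calorie model
#'
#' @param params [ga_params()] or a [fit_ga()] result.
#' @param income per-capita income (> 0), US$2005 capita^-1 a^-1.
#' @param year calendar year.
#' @return kcal capita^-1 d^-1.
#' @export
eval_ga <- function(params, income, year) {
  if (any(income <= 0)) stop_data("income must be > 0")
  exp(params$alpha1 + params$alpha2 * year) *
    income^(params$beta1 + params$beta2 * year)
}

#' Evaluate a saturating time trajectory
#'
#' @param params [mm_params()].
#' @param year calendar year.
#' @return trajectory value `omega1 + omega2 (t - t1)/(t - t1 + omega3)`.
#' @export
eval_mm <- function(params, year) {
  dt <- year - params$t1
  den <- dt + params$omega3
  if (any(abs(den) < 1e-9)) {
    stop_data("saturating trajectory evaluated at its pole (t - t1 + omega3 = 0)")
  }
  params$omega1 + params$omega2 * dt / den
}

#' Fit a saturating time trajectory to a coefficient series
#'
#' Nonlinear least squares for `m(t) = omega1 + omega2 (t-t1)/(t-t1+omega3)`.
#' Deterministic multi-start: `omega1` at the first value, `omega2` at the
#' last-minus-first difference, and `omega3` swept over a fixed grid of
#' half-saturation scales (the best converged start by residual sum of
#' squares wins), because the half-saturation constant may legitimately be
#' small or negative. A series with negligible spread short-circuits to
#' `omega2 = 0` with a warning.
#'
#' @param series data.frame with columns `year` and `value` (>= 4 points).
#' @param t1 base year of the trajectory (default 1960).
#' @return [mm_params()] with fit diagnostics attached.
#' @export
fit_michaelis_menten <- function(series, t1 = 1960) {
  if (!all(c("year", "value") %in% names(series))) {
    stop_data("series needs columns 'year' and 'value'")
  }
  series <- series[!is.na(series$value), , drop = FALSE]
  n <- nrow(series)
  if (n < 4L) stop_data(sprintf("need >= 4 points, got %d", n))

  scale <- max(abs(series$value), 1e-12)
  if (diff(range(series$value)) < 1e-10 * scale) {
    warning("flat series: returning omega2 = 0")
    out <- mm_params(mean(series$value), 0, diff(range(series$year)) / 2,
                     t1 = t1)
    attr(out, "diagnostics") <- list(rse = 0, n = n, flat = TRUE)
    return(out)
  }

  span <- diff(range(series$year))
  d <- data.frame(dt = series$year - t1, value = series$value)

  ## The model is linear in (omega1, omega2) once omega3 is fixed, so each
  ## candidate half-saturation constant is scored by its exact profiled
  ## least-squares solution; the best few candidates seed the joint
  ## Levenberg-Marquardt refinement. The grid covers fast positive
  ## saturation, span-scale saturation, and the small negative values that
  ## produce decreasing trajectories (poles at omega3 = -dt are skipped).
  candidates <- sort(unique(c(
    seq(-0.95, -0.05, by = 0.1), seq(0.05, 1.05, by = 0.1),
    -c(1.5, 2.5, 5.5), 1.5, 2.5, 4, 7, 12, 20, 35,
    span * c(0.25, 0.5, 1, 2))))
  profile_fit <- function(w3) {
    if (min(abs(d$dt + w3)) < 1e-6) return(NULL)
    u <- d$dt / (d$dt + w3)
    if (sd(u) < 1e-12) return(NULL)
    lf <- lm(value ~ u, data = d)
    list(w1 = unname(coef(lf)[1L]), w2 = unname(coef(lf)[2L]), w3 = w3,
         rss = sum(resid(lf)^2))
  }
  profiles <- Filter(Negate(is.null), lapply(candidates, profile_fit))
  if (length(profiles) == 0L) {
    stop_numeric("no admissible half-saturation start for the trajectory fit")
  }
  profiles <- profiles[order(vapply(profiles, `[[`, numeric(1L), "rss"))]

  best <- NULL
  for (start in profiles[seq_len(min(5L, length(profiles)))]) {
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ w1 + w2 * dt / (dt + w3), data = d,
                        start = start[c("w1", "w2", "w3")],
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop_numeric("saturating-trajectory fit did not converge from any start")
  }
  cc <- coef(best$fit)
  out <- mm_params(unname(cc["w1"]), unname(cc["w2"]), unname(cc["w3"]),
                   t1 = t1)
  attr(out, "diagnostics") <- list(
    rse = sqrt(best$rss / max(1L, n - 3L)), n = n, flat = FALSE)
  out
}

#' Fit the saturating-time total-calorie model
#'
#' Stage 1 runs [fit_yearly_power()] for every year with at least 3
#' complete pairs; stage 2 fits saturating trajectories
#' ([fit_michaelis_menten()]) to the yearly `alpha` and `beta` series.
#'
#' @param panel a [food_panel()].
#' @param t1 base year of the trajectories (default 1960).
#' @return object of class `c("gb_fit", "gb_params")` with the per-year
#'   coefficient table (`$yearly`) and stage diagnostics.
#' @export
fit_gb <- function(panel, t1 = 1960) {
  d <- complete_total_rows(panel)
  counts <- table(d$year)
  usable <- sort(as.integer(names(counts)[counts >= 3L]))
  if (length(usable) < 2L) {
    stop_data("need at least 2 years with >= 3 complete pairs each")
  }
  yearly <- lapply(usable, function(y) {
    fit <- tryCatch(fit_yearly_power(d[d$year == y, , drop = FALSE]),
                    error = function(e) {
                      warning("yearly fit failed for year ", y, "; excluded")
                      NULL
                    })
    if (is.null(fit)) return(NULL)
    data.frame(year = y, alpha = fit$alpha, beta = fit$beta,
               rse = fit$rse, n = fit$n)
  })
  yearly <- do.call(rbind, yearly)
  if (is.null(yearly) || nrow(yearly) < 4L) {
    stop_data("fewer than 4 years survived the yearly power-law stage")
  }
  m_alpha <- fit_michaelis_menten(
    data.frame(year = yearly$year, value = yearly$alpha), t1 = t1)
  m_beta <- fit_michaelis_menten(
    data.frame(year = yearly$year, value = yearly$beta), t1 = t1)
  out <- gb_params(m_alpha, m_beta)
  out$yearly <- yearly
  attr(out, "diagnostics") <- list(
    rse_alpha = attr(m_alpha, "diagnostics")$rse,
    rse_beta = attr(m_beta, "diagnostics")$rse,
    n_years = nrow(yearly), n_obs = sum(yearly$n))
  class(out) <- c("gb_fit", class(out))
  out
}

#' Evaluate the saturating-time total-calorie model
#'
#' @param params [gb_params()] or a [fit_gb()] result.
#' @param income per-capita income (> 0), US$2005 capita^-1 a^-1.
#' @param year calendar year.
#' @return kcal capita^-1 d^-1.
#' @export
eval_gb <- function(params, income, year) {
  if (any(income <= 0)) stop_data("income must be > 0")
  eval_mm(params$m_alpha, year) * income^eval_mm(params$m_beta, year)
}
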