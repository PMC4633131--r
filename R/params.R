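## Parameter containers for the four demand regression families, the
## shared evaluation generic, reference coefficient sets, and a flat
## key-value serialization so fitted parameters are diffable.

#' Parameters of the linear-time total-calorie model
#'
#' The total-calorie Engel curve `C_T = alpha * I^beta` with log-scale
#' intercept `alpha* = ln(alpha)` and elasticity `beta` both linear in
#' calendar year `t`:
#' `g_A(I, t) = exp(alpha1 + alpha2 t) * I^(beta1 + beta2 t)`.
#'
#' @param alpha1,alpha2 intercept and per-year slope of `alpha* = ln(alpha)`.
#' @param beta1,beta2 intercept and per-year slope of the income
#'   elasticity `beta`.
#' @param year_range optional span over which the evaluated elasticity is
#'   expected to stay in (0, 1); a value outside it triggers a warning.
#' @return object of class `ga_params`.
#' @export
ga_params <- function(alpha1, alpha2, beta1, beta2, year_range = NULL) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2,
            beta1 = beta1, beta2 = beta2)
  if (any(!vapply(p, is.finite, logical(1L)))) {
    stop_data("ga_params coefficients must be finite")
  }
  if (!is.null(year_range)) {
    beta_ends <- beta1 + beta2 * year_range
    if (any(beta_ends <= 0 | beta_ends >= 1)) {
      warning("evaluated elasticity leaves (0, 1) inside the declared ",
              "year range")
    }
  }
  structure(p, year_range = year_range, class = "ga_params")
}

#' Parameters of a saturating (Michaelis-Menten-type) time trajectory
#'
#' `m(t) = omega1 + omega2 * (t - t1) / (t - t1 + omega3)`, the saturating
#' curve used for the time paths of the yearly power-law coefficients:
#' intercept `omega1`, asymptotic increment `omega2`, half-saturation
#' constant `omega3` (years), base year `t1`.
#'
#' @param omega1,omega2,omega3 curve coefficients.
#' @param t1 base year (default 1960).
#' @return object of class `mm_params`.
#' @export
mm_params <- function(omega1, omega2, omega3, t1 = 1960) {
  p <- list(omega1 = omega1, omega2 = omega2, omega3 = omega3, t1 = t1)
  if (any(!vapply(p, is.finite, logical(1L)))) {
    stop_data("mm_params coefficients must be finite")
  }
  structure(p, class = "mm_params")
}

#' Parameters of the saturating-time total-calorie model
#'
#' `g_B(I, t) = m_alpha(t) * I^(m_beta(t))` where both coefficient
#' trajectories are saturating curves ([mm_params()]).
#'
#' @param m_alpha,m_beta [mm_params()] trajectories for the scale and
#'   elasticity coefficients.
#' @return object of class `gb_params`.
#' @export
gb_params <- function(m_alpha, m_beta) {
  stopifnot(inherits(m_alpha, "mm_params"), inherits(m_beta, "mm_params"))
  structure(list(m_alpha = m_alpha, m_beta = m_beta), class = "gb_params")
}

#' Parameters of the log-linear animal-share model
#'
#' `h_A(I, t) = exp(kappa1 + kappa2 ln I + kappa3 t + kappa4 ln(I) t)`,
#' with `t` in calendar years. Rising income raises the share (Bennet's
#' law) while the negative income-time interaction bends it down in later
#' years at high incomes.
#'
#' @param kappa1,kappa2,kappa3,kappa4 regression coefficients.
#' @return object of class `ha_params`.
#' @export
ha_params <- function(kappa1, kappa2, kappa3, kappa4) {
  p <- list(kappa1 = kappa1, kappa2 = kappa2,
            kappa3 = kappa3, kappa4 = kappa4)
  if (any(!vapply(p, is.finite, logical(1L)))) {
    stop_data("ha_params coefficients must be finite")
  }
  structure(p, class = "ha_params")
}

#' Parameters of the peaked animal-share model
#'
#' `h_B(I, t) = (rho1 + rho2 t) * sqrt(I) * exp(-(lambda1 + lambda2 t) I)`:
#' an under-proportionally increasing square-root rise multiplied by an
#' exponential decline, so the share peaks at `I* = 1 / (2 lambda(t))` and
#' falls toward zero at high incomes without going negative.
#'
#' @param rho1,rho2 level coefficients (per sqrt(US$)); `rho(t) = rho1 +
#'   rho2 t` must stay positive over the evaluation range.
#' @param lambda1,lambda2 decay coefficients (per US$); `lambda(t)` must
#'   stay positive over the evaluation range.
#' @return object of class `hb_params`.
#' @export
hb_params <- function(rho1, rho2, lambda1, lambda2) {
  p <- list(rho1 = rho1, rho2 = rho2, lambda1 = lambda1, lambda2 = lambda2)
  if (any(!vapply(p, is.finite, logical(1L)))) {
    stop_data("hb_params coefficients must be finite")
  }
  structure(p, class = "hb_params")
}

#' Reference coefficient sets for the four demand models
#'
#' Coefficients estimated from the historical FAOSTAT/WDI panel
#' (1961-2007, 162 countries, incomes in US$2005 capita^-1 a^-1, calendar
#' year time convention). They drive the "historical-like" synthetic-data
#' presets and the worked examples, so that fitting and projection can be
#' exercised without downloading the source databases.
#'
#' @param model one of `"gA"`, `"gB"`, `"hA"`, `"hB"`.
#' @return the corresponding parameter object.
#' @examples
#' eval_model(reference_params("gB"), income = 60000, year = 2000)
#' @export
reference_params <- function(model = c("gA", "gB", "hA", "hB")) {
  model <- match.arg(model)
  switch(model,
    gA = ga_params(alpha1 = 2.825, alpha2 = 2.131e-3,
                   beta1 = 0.162, beta2 = -3.124e-5,
                   year_range = c(1961, 2100)),
    gB = gb_params(
      m_alpha = mm_params(9.339e2, 3.875e2, 9.775, t1 = 1960),
      m_beta  = mm_params(8.941e-2, 8.445e-3, -7.557e-1, t1 = 1960)),
    hA = ha_params(kappa1 = -3.673e1, kappa2 = 4.497,
                   kappa3 = 1.604e-2, kappa4 = -2.077e-3),
    hB = hb_params(rho1 = 1.372e-2, rho2 = -5.295e-6,
                   lambda1 = -1.102e-4, lambda2 = 6.404e-8))
}

#' Evaluated coefficient trajectories of a demand model
#'
#' Returns the model's time-varying coefficients evaluated on a year
#' grid: `alpha*(t)` and `beta(t)` for the linear-time total-calorie
#' model, `m_alpha(t)` and `m_beta(t)` for the saturating-time model,
#' `rho(t)` and `lambda(t)` for the peaked share model; the log-linear
#' share model has constant coefficients, returned as-is. These are the
#' identifiable quantities on which parameter recovery is assessed: the
#' raw intercept/slope pairs of the time-linear models sit at calendar
#' year zero, far outside any observation window, and are nearly
#' collinear there.
#'
#' @param params a parameter object.
#' @param years year grid over which to evaluate.
#' @return named numeric vector of trajectory values.
#' @export
coef_trajectories <- function(params, years) {
  id <- model_id(params)
  switch(id,
    gA = c(setNames(params$alpha1 + params$alpha2 * years,
                    paste0("alpha_star.", years)),
           setNames(params$beta1 + params$beta2 * years,
                    paste0("beta.", years))),
    gB = c(setNames(eval_mm(params$m_alpha, years),
                    paste0("m_alpha.", years)),
           setNames(eval_mm(params$m_beta, years),
                    paste0("m_beta.", years))),
    hA = coef(params),
    hB = c(setNames(params$rho1 + params$rho2 * years,
                    paste0("rho.", years)),
           setNames(params$lambda1 + params$lambda2 * years,
                    paste0("lambda.", years))))
}

model_id <- function(params) {
  if (inherits(params, "ga_params")) return("gA")
  if (inherits(params, "gb_params")) return("gB")
  if (inherits(params, "ha_params")) return("hA")
  if (inherits(params, "hb_params")) return("hB")
  stop_data("unknown parameter class")
}

#' Evaluate a demand model
#'
#' Common front door for the four regression families: dispatches to
#' [eval_ga()], [eval_gb()], [eval_ha()] or [eval_hb()] on the class of
#' `params`. Total-calorie models return kcal capita^-1 d^-1; share
#' models return a dimensionless fraction.
#'
#' @param params a fitted or constructed parameter object.
#' @param income per-capita income, US$2005 capita^-1 a^-1 (> 0).
#' @param year calendar year.
#' @param ... passed to the specific evaluator (share models accept
#'   `on_exceed`).
#' @return numeric vector of model values.
#' @export
eval_model <- function(params, income, year, ...) {
  UseMethod("eval_model")
}

#' @export
eval_model.ga_params <- function(params, income, year, ...) {
  eval_ga(params, income, year)
}

#' @export
eval_model.gb_params <- function(params, income, year, ...) {
  eval_gb(params, income, year)
}

#' @export
eval_model.ha_params <- function(params, income, year, ...) {
  eval_ha(params, income, year, ...)
}

#' @export
eval_model.hb_params <- function(params, income, year, ...) {
  eval_hb(params, income, year, ...)
}

#' @export
coef.ga_params <- function(object, ...) {
  unlist(object[c("alpha1", "alpha2", "beta1", "beta2")])
}

#' @export
coef.mm_params <- function(object, ...) {
  unlist(object[c("omega1", "omega2", "omega3")])
}

#' @export
coef.gb_params <- function(object, ...) {
  c(setNames(coef(object$m_alpha),
             paste0("m_alpha.", names(coef(object$m_alpha)))),
    setNames(coef(object$m_beta),
             paste0("m_beta.", names(coef(object$m_beta)))))
}

#' @export
coef.ha_params <- function(object, ...) {
  unlist(object[c("kappa1", "kappa2", "kappa3", "kappa4")])
}

#' @export
coef.hb_params <- function(object, ...) {
  unlist(object[c("rho1", "rho2", "lambda1", "lambda2")])
}

#' Serialize fitted parameters to a flat key-value text file
#'
#' One `key value` pair per line (space separated, 17 significant digits),
#' with the model id on the first line, so parameter files diff cleanly
#' between runs. Stage diagnostics stored on fit objects are written as
#' `diag.*` keys and restored as attributes.
#'
#' @param params a parameter object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  lines <- c(paste("model", model_id(params)))
  cc <- coef(params)
  lines <- c(lines, paste(names(cc), sprintf("%.17g", cc)))
  if (inherits(params, "gb_params")) {
    lines <- c(lines,
               paste("m_alpha.t1", params$m_alpha$t1),
               paste("m_beta.t1", params$m_beta$t1))
  }
  diags <- attr(params, "diagnostics")
  if (!is.null(diags)) {
    dv <- unlist(diags)
    dv <- dv[!is.na(suppressWarnings(as.numeric(dv)))]
    lines <- c(lines, paste(paste0("diag.", names(dv)),
                            vapply(as.numeric(dv),
                                   function(v) sprintf("%.17g", v), "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read parameters from a flat key-value text file
#'
#' @param path file written by [write_params()].
#' @return the reconstructed parameter object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  keys <- vapply(parts, `[`, character(1L), 1L)
  vals <- vapply(parts, `[`, character(1L), 2L)
  model <- vals[keys == "model"]
  kv <- setNames(suppressWarnings(as.numeric(vals)), keys)
  kv <- kv[keys != "model"]
  diags <- kv[startsWith(names(kv), "diag.")]
  kv <- kv[!startsWith(names(kv), "diag.")]
  params <- switch(model,
    gA = ga_params(kv[["alpha1"]], kv[["alpha2"]],
                   kv[["beta1"]], kv[["beta2"]]),
    gB = gb_params(
      mm_params(kv[["m_alpha.omega1"]], kv[["m_alpha.omega2"]],
                kv[["m_alpha.omega3"]], t1 = kv[["m_alpha.t1"]]),
      mm_params(kv[["m_beta.omega1"]], kv[["m_beta.omega2"]],
                kv[["m_beta.omega3"]], t1 = kv[["m_beta.t1"]])),
    hA = ha_params(kv[["kappa1"]], kv[["kappa2"]],
                   kv[["kappa3"]], kv[["kappa4"]]),
    hB = hb_params(kv[["rho1"]], kv[["rho2"]],
                   kv[["lambda1"]], kv[["lambda2"]]),
    stop_data(paste0("unknown model id in parameter file: ", model)))
  if (length(diags) > 0L) {
    attr(params, "diagnostics") <-
      setNames(as.list(diags), sub("^diag\\.", "", names(diags)))
  }
  params
}

#' @export
print.ga_params <- function(x, ...) {
  cat("<gA> total calories, linear time dependence\n")
  cat(sprintf("  ln(alpha) = %.6g + %.6g t;  beta = %.6g + %.6g t\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  invisible(x)
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf(
    "<mm> m(t) = %.6g + %.6g (t-%d)/(t-%d+%.6g)\n",
    x$omega1, x$omega2, x$t1, x$t1, x$omega3))
  invisible(x)
}

#' @export
print.gb_params <- function(x, ...) {
  cat("<gB> total calories, saturating time dependence\n  alpha: ")
  print(x$m_alpha)
  cat("  beta:  ")
  print(x$m_beta)
  invisible(x)
}

#' @export
print.ha_params <- function(x, ...) {
  cat("<hA> animal share, log-linear with income x time interaction\n")
  cat(sprintf("  kappa = (%.6g, %.6g, %.6g, %.6g)\n",
              x$kappa1, x$kappa2, x$kappa3, x$kappa4))
  invisible(x)
}

#' @export
print.hb_params <- function(x, ...) {
  cat("<hB> animal share, peaked sqrt x exponential decay\n")
  cat(sprintf("  rho(t) = %.6g + %.6g t;  lambda(t) = %.6g + %.6g t\n",
              x$rho1, x$rho2, x$lambda1, x$lambda2))
  invisible(x)
}
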