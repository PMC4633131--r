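## Scenario engine: storyline-to-model binding, per-capita projection,
## convergence calibration to base-year observations, total-energy
## conversion and population-weighted regional aggregation.

#' Construct a scenario input
#'
#' Per-country income and population trajectories on a common time grid
#' (canonically 1990-2100 in 5-year steps), tagged with a storyline.
#'
#' @param trajectory data.frame with columns `country`, `year`, `income`
#'   (> 0) and `population` (>= 0).
#' @param storyline tag, e.g. `"A1"`, `"A2"`, `"B1"`, `"B2"` or a custom
#'   label.
#' @return object of class `scenario_input`.
#' @export
scenario_input <- function(trajectory, storyline = "custom") {
  need <- c("country", "year", "income", "population")
  if (!all(need %in% names(trajectory))) {
    stop_data(paste0("scenario trajectory needs columns: ",
                     paste(need, collapse = ", ")))
  }
  trajectory <- trajectory[need]
  if (any(trajectory$income <= 0, na.rm = TRUE)) {
    stop_data("projected income must be > 0")
  }
  if (any(trajectory$population < 0, na.rm = TRUE)) {
    stop_data("projected population must be >= 0")
  }
  grids <- split(trajectory$year, trajectory$country)
  if (any(vapply(grids, function(y) any(diff(sort(y)) <= 0) || anyDuplicated(y) > 0,
                 logical(1L)))) {
    stop_data("each country's time grid must be strictly increasing")
  }
  structure(list(storyline = storyline, trajectory = trajectory),
            class = "scenario_input")
}

#' Bind a storyline to its pair of demand models
#'
#' The materialistic storylines (A1, A2) use the linear-time total-calorie
#' model and the log-linear share model, whose long-run consumption levels
#' are higher; the sustainability-oriented storylines (B1, B2) use the
#' saturating-time total-calorie model and the peaked share model, which
#' level off or decline in the long run. Custom tags take an explicit
#' model pair.
#'
#' @param tag storyline tag.
#' @param params named list of fitted parameter objects; for the four
#'   canonical tags it must contain the required entries (`gA` and `hA`,
#'   or `gB` and `hB`); for other tags supply `total` and `share`
#'   explicitly.
#' @param total,share explicit parameter objects for custom tags.
#' @return list of class `storyline_binding` with elements `tag`, `total`
#'   and `share`.
#' @export
bind_storyline <- function(tag, params = NULL, total = NULL, share = NULL) {
  if (tag %in% c("A1", "A2")) {
    total <- total %||% params$gA
    share <- share %||% params$hA
  } else if (tag %in% c("B1", "B2")) {
    total <- total %||% params$gB
    share <- share %||% params$hB
  }
  if (is.null(total) || is.null(share)) {
    stop_config(paste0("storyline '", tag,
                       "' needs an explicit (total, share) model pair ",
                       "or fitted parameters in `params`"))
  }
  if (!model_id(total) %in% c("gA", "gB")) {
    stop_config("`total` must be a total-calorie parameter object")
  }
  if (!model_id(share) %in% c("hA", "hB")) {
    stop_config("`share` must be a share parameter object")
  }
  structure(list(tag = tag, total = total, share = share),
            class = "storyline_binding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project raw per-capita vegetal and animal demand
#'
#' Evaluates the bound total-calorie and share models on the scenario's
#' income path: vegetal demand is `g(I, t) (1 - h(I, t))` and animal
#' demand `g(I, t) h(I, t)`, so their sum equals the total exactly. A
#' share outside \[0, 1\] aborts the projection rather than being clipped
#' silently, since `1 - h` would go negative.
#'
#' @param binding a [bind_storyline()] result.
#' @param scenario a [scenario_input()].
#' @return data.frame with columns `country`, `year`, `income`,
#'   `population`, `total_percap`, `share`, `veg_percap`, `animal_percap`
#'   (per-capita values in kcal capita^-1 d^-1).
#' @export
project_percap <- function(binding, scenario) {
  tr <- scenario$trajectory
  total <- eval_model(binding$total, tr$income, tr$year)
  share <- eval_model(binding$share, tr$income, tr$year, on_exceed = "error")
  data.frame(country = tr$country, year = tr$year, income = tr$income,
             population = tr$population, total_percap = total,
             share = share, veg_percap = total * (1 - share),
             animal_percap = total * share)
}

#' Linear convergence blend between observation and projection
#'
#' For `t` in `[ys, ye]` returns
#' `((t - ys) x + (ye - t) c0) / (ye - ys)`: the observed base-year value
#' `c0` exactly at `t = ys`, the raw projection `x` exactly at `t = ye`,
#' and a linear blend in between. Beyond `ye` the projection is returned
#' unchanged.
#'
#' @param x projected value(s) at time `t`.
#' @param c0 observed base-year value(s).
#' @param ys base (start) year.
#' @param ye convergence (end) year.
#' @param t evaluation year(s), `t >= ys`.
#' @return calibrated value(s).
#' @export
conv <- function(x, c0, ys, ye, t) {
  if (ys >= ye) stop_config("base year must precede convergence year")
  if (any(t < ys)) stop_data("conv is undefined before the base year")
  ifelse(t > ye, x, ((t - ys) * x + (ye - t) * c0) / (ye - ys))
}

#' Calibrate projected per-capita demand to base-year observations
#'
#' Two calibration modes, applied to the vegetal and animal series
#' separately (preserving vegetal + animal = total by construction):
#'
#' * `"converge"`: [conv()] blends each country's projection with its
#'   observed base-year value, so national peculiarities present in the
#'   base year fade linearly and vanish by the convergence year.
#' * `"preserve"`: each country keeps its base-year ratio of observed to
#'   projected demand at all times, so a country 10% above the regression
#'   in the base year stays 10% above throughout.
#'
#' @param projections output of [project_percap()], covering the base year.
#' @param observed data.frame with columns `country`, `veg_cal`,
#'   `animal_cal`: observed base-year per-capita values for every country.
#' @param base_year year at which projections must meet observations
#'   (default 1990).
#' @param conv_year year by which converge-mode projections reach the
#'   regression surface (default 2100).
#' @param mode `"converge"` (default) or `"preserve"`.
#' @return `projections` with columns `veg_calib`, `animal_calib` and
#'   `total_calib` appended.
#' @export
calibrate <- function(projections, observed,
                      base_year = 1990, conv_year = 2100,
                      mode = c("converge", "preserve")) {
  mode <- match.arg(mode)
  need <- c("country", "veg_cal", "animal_cal")
  if (!all(need %in% names(observed))) {
    stop_data("observed base-year table needs columns country, veg_cal, animal_cal")
  }
  idx <- match(projections$country, observed$country)
  if (anyNA(idx)) {
    miss <- unique(projections$country[is.na(idx)])
    stop_data(paste0("missing base-year observation for: ",
                     paste(head(miss, 5L), collapse = ", ")))
  }
  obs_veg <- observed$veg_cal[idx]
  obs_anim <- observed$animal_cal[idx]
  if (any(obs_veg < 0 | obs_anim < 0, na.rm = TRUE)) {
    stop_data("observed base-year values must be >= 0")
  }

  if (mode == "converge") {
    projections$veg_calib <- conv(projections$veg_percap, obs_veg,
                                  base_year, conv_year, projections$year)
    projections$animal_calib <- conv(projections$animal_percap, obs_anim,
                                     base_year, conv_year, projections$year)
  } else {
    base <- projections[projections$year == base_year, , drop = FALSE]
    if (nrow(base) == 0L) {
      stop_data("preserve mode needs projections at the base year")
    }
    bidx <- match(projections$country, base$country)
    if (anyNA(bidx)) {
      stop_data("preserve mode needs a base-year projection for every country")
    }
    oidx <- match(base$country, observed$country)
    ratio_veg <- (observed$veg_cal[oidx] / base$veg_percap)[bidx]
    ratio_anim <- (observed$animal_cal[oidx] / base$animal_percap)[bidx]
    projections$veg_calib <- projections$veg_percap * ratio_veg
    projections$animal_calib <- projections$animal_percap * ratio_anim
  }
  projections$total_calib <- projections$veg_calib + projections$animal_calib
  projections
}

#' Total national food energy demand
#'
#' Multiplies calibrated per-capita demand by projected population and
#' converts to annual energy: `E = C * P * kcal_to_joule * days_per_year`,
#' reported in 10^18 J a^-1. The energy constants are explicit because
#' reported totals depend on them.
#'
#' @param calibrated output of [calibrate()] (needs `veg_calib`,
#'   `animal_calib`, `population`).
#' @param kcal_to_joule J per kcal (default 4184).
#' @param days_per_year days per year (default 365).
#' @return `calibrated` with columns `energy_veg` and `energy_animal`
#'   (10^18 J a^-1) appended.
#' @export
demand_totals <- function(calibrated, kcal_to_joule = 4184,
                          days_per_year = 365) {
  need <- c("veg_calib", "animal_calib", "population")
  if (!all(need %in% names(calibrated))) {
    stop_data("calibrated table needs veg_calib, animal_calib, population")
  }
  if (any(calibrated$veg_calib < 0 | calibrated$animal_calib < 0 |
            calibrated$population < 0, na.rm = TRUE)) {
    stop_data("negative inputs to total-demand conversion")
  }
  k <- kcal_to_joule * days_per_year / 1e18
  calibrated$energy_veg <- calibrated$veg_calib * calibrated$population * k
  calibrated$energy_animal <-
    calibrated$animal_calib * calibrated$population * k
  calibrated
}

#' Aggregate a projection table to regions
#'
#' Per-capita variables become population-weighted regional means; total
#' energy variables and population are summed.
#'
#' @param table a country-level projection table with `country`, `year`,
#'   `population` and the columns to aggregate.
#' @param map a [region_map()] covering every country in `table`.
#' @param percap_cols per-capita columns to average (defaults to those
#'   present among the standard per-capita columns).
#' @param total_cols extensive columns to sum (defaults to the energy
#'   columns present).
#' @return data.frame with one row per region-year.
#' @export
aggregate_regions <- function(table, map,
                              percap_cols = NULL, total_cols = NULL) {
  map <- region_map(map)
  region <- map$region[match(table$country, map$country)]
  if (anyNA(region)) {
    miss <- unique(table$country[is.na(region)])
    stop_data(paste0("countries without region mapping: ",
                     paste(head(miss, 5L), collapse = ", ")))
  }
  if (is.null(percap_cols)) {
    percap_cols <- intersect(
      c("income", "total_percap", "share", "veg_percap", "animal_percap",
        "veg_calib", "animal_calib", "total_calib"), names(table))
  }
  if (is.null(total_cols)) {
    total_cols <- intersect(c("energy_veg", "energy_animal"), names(table))
  }
  key <- interaction(region, table$year, drop = TRUE)
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(i) {
    out <- data.frame(region = region[i][1L], year = table$year[i][1L],
                      population = sum(table$population[i]))
    for (col in percap_cols) {
      out[[col]] <- weighted.mean(table[[col]][i], table$population[i])
    }
    for (col in total_cols) out[[col]] <- sum(table[[col]][i])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a full demand scenario from a declarative configuration
#'
#' Ties the pipeline together: bind the storyline's models, project raw
#' per-capita demand on the scenario's income path, calibrate to observed
#' base-year values, convert to total energy, and (when a region map is
#' given) aggregate regionally. With `out_dir` set, writes one CSV per
#' stage plus a `manifest.json` recording the configuration, constants
#' and package version; floating-point output uses 12 significant digits
#' so repeated runs diff cleanly.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `storyline`; `params` (named list of parameter objects, or paths to
#'   files written by [write_params()]); `scenario` (a [scenario_input()],
#'   a trajectory data.frame, or a CSV path); `observed` (base-year
#'   observation table or CSV path); optional `calibration` (list with
#'   `mode`, `base_year`, `conv_year`); optional `region_map`; optional
#'   `constants` (`kcal_to_joule`, `days_per_year`); optional `out_dir`.
#' @return invisible list with `percap`, `calibrated`, `regional` (or
#'   NULL) and `manifest`.
#' @export
run_scenario <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config(paste0("config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  for (field in c("storyline", "params", "scenario", "observed")) {
    if (is.null(config[[field]])) {
      stop_config(paste0("config is missing required field '", field, "'"))
    }
  }
  params <- lapply(config$params, function(p) {
    if (is.character(p)) read_params(p) else p
  })
  scen <- config$scenario
  if (is.character(scen)) {
    scen <- read.csv(scen)
  }
  if (!inherits(scen, "scenario_input")) {
    scen <- scenario_input(scen, storyline = config$storyline)
  }
  observed <- config$observed
  if (is.character(observed)) observed <- read.csv(observed)

  cal <- modifyList(list(mode = "converge", base_year = 1990,
                         conv_year = 2100),
                    config$calibration %||% list())
  const <- modifyList(list(kcal_to_joule = 4184, days_per_year = 365),
                      config$constants %||% list())

  binding <- bind_storyline(config$storyline, params = params)
  percap <- project_percap(binding, scen)
  calib <- calibrate(percap, observed, base_year = cal$base_year,
                     conv_year = cal$conv_year, mode = cal$mode)
  calib <- demand_totals(calib, kcal_to_joule = const$kcal_to_joule,
                         days_per_year = const$days_per_year)
  regional <- NULL
  if (!is.null(config$region_map)) {
    regional <- aggregate_regions(calib, config$region_map)
  }

  manifest <- list(
    storyline = config$storyline,
    models = list(total = model_id(binding$total),
                  share = model_id(binding$share)),
    coefficients = lapply(
      list(total = binding$total, share = binding$share), coef),
    calibration = cal, constants = const,
    n_countries = length(unique(scen$trajectory$country)),
    years = range(scen$trajectory$year),
    seed = config$seed %||% NA,
    package_version = as.character(utils::packageVersion("fooddemand")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_csv(percap, file.path(config$out_dir, "percap.csv"))
    write_stage_csv(calib, file.path(config$out_dir, "calibrated.csv"))
    if (!is.null(regional)) {
      write_stage_csv(regional, file.path(config$out_dir, "regional.csv"))
    }
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(percap = percap, calibrated = calib, regional = regional,
                 manifest = manifest))
}

## stage outputs at 12 significant digits for stable diffs
write_stage_csv <- function(x, path) {
  for (col in names(x)) {
    if (is.double(x[[col]])) {
      x[[col]] <- formatC(x[[col]], digits = 12, format = "g")
    }
  }
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
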