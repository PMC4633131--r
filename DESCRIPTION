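Package: fooddemand
Title: Long-Term National Food Demand Scenarios from Income and
    Population Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs long-term (to 2100) national and regional
    scenarios of per-capita and total food calorie demand from exogenous
    income and population projections.  Fits four time-dependent
    regression families linking per-capita income to total calorie
    demand (a log-log Engel curve with linearly time-varying
    coefficients, and yearly power-law fits whose coefficients follow
    saturating Michaelis-Menten-type time trajectories) and to the
    animal-based calorie share (a log-linear model with an income-time
    interaction, and a peaked square-root times exponential-decay form).
    Includes panel harmonization (deflation, regional gap filling,
    coverage exclusion), storyline-based scenario projection with
    convergence calibration to base-year observations, population
    weighted regional aggregation, Mann-Kendall trend testing, bootstrap
    subsample sensitivity analysis, and a synthetic panel generator for
    end-to-end testing without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
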