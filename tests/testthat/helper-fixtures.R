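# Shared fixtures: small panels built in code, reference parameter sets,
# and relative-error helpers.

ref <- list(gA = reference_params("gA"), gB = reference_params("gB"),
            hA = reference_params("hA"), hB = reference_params("hB"))

rel_err <- function(x, target) abs(x / target - 1)

# tiny hand-built panel: 3 countries x 2 years, all values present
tiny_panel <- function() {
  food_panel(data.frame(
    country = rep(c("AAA", "BBB", "CCC"), 2),
    year = rep(c(1990L, 1991L), each = 3),
    income = c(500, 5000, 20000, 520, 5100, 20500),
    population = c(1e6, 5e6, 2e7, 1.02e6, 5.05e6, 2.01e7),
    total_cal = c(2100, 2700, 3300, 2120, 2710, 3310),
    animal_cal = c(150, 500, 900, 155, 510, 905)))
}

# noiseless world on the reference gA/hA surfaces (small, fast)
clean_panel_ga <- function(n = 30, seed = 7) {
  gen_panel(synth_spec(n_countries = n, sigma_total = 0, sigma_share = 0,
                       seed = seed))
}

# noiseless world on the reference gB/hB surfaces
clean_panel_gb <- function(n = 30, seed = 7) {
  gen_panel(synth_spec(n_countries = n,
                       total_model = reference_params("gB"),
                       share_model = reference_params("hB"),
                       sigma_total = 0, sigma_share = 0, seed = seed))
}

# drop bookkeeping attributes so record equality can be compared
plain_records <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names")]
  class(x) <- "data.frame"
  x
}

# brute-force Mann-Kendall S by explicit double loop (independent of the
# vectorised implementation path)
brute_mk_s <- function(v) {
  n <- length(v)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(v[j] - v[i])
  }
  s
}
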