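# Shared fixtures: desk-scale configurations and a hand-built simulation
# object for exercising the analysis functions on known numbers.

desk_config <- function(scenario = "B", n_repetitions = 1, ...) {
  scenario_config(
    scenario,
    n_repetitions = n_repetitions, n_founders = 80,
    n_generations = 2, n_pregenerations = 1,
    adult_years = 10, repro_start = 6,
    ...
  )
}

# A flat climate: constant temperatures, daily drizzle, no frost.
flat_climate <- function(t_mean = 10, t_min = t_mean - 4, precip = 2,
                         n_years = 1, ref = 1000) {
  out <- tidyr::expand_grid(year = seq_len(n_years), doy = 1:365)
  out$t_mean <- t_mean
  out$t_min <- t_min
  out$precip <- precip
  out$radiation <- 15
  attr(out, "reference_elevation") <- ref
  out
}

# Minimal phenoevo_sim skeleton from explicit per-generation tables, for
# analysis-function oracles.
fake_sim <- function(reps) {
  structure(
    list(config = scenario_config("B", n_repetitions = length(reps)),
         reps = reps, seed = 0L),
    class = "phenoevo_sim"
  )
}

fake_generation <- function(generation, f_crit, band = "Alt3",
                            elevation = 1200, survivor_ids = integer(0),
                            band_years = NULL) {
  n <- length(f_crit)
  cohort <- tibble::tibble(
    id = seq_len(n),
    x = 100, y = elevation - 700, elevation = elevation,
    age = 40L, dbh = 13.8, height = 9, crown_area = 11.7,
    g_value = f_crit, f_crit = f_crit,
    mother = NA_integer_, father = NA_integer_,
    genotype_str = strrep("1", 10),
    band = factor(band, levels = paste0("Alt", 1:5))
  )
  list(
    generation = generation,
    cohort = cohort,
    survivors = tibble::tibble(tree_id = survivor_ids),
    band_years = band_years,
    deaths = tibble::tibble(),
    annual = NULL
  )
}
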