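# Simulation engine: scenario presets, initialization, neutral pre-evolution
# and the generation loop coupling physiology, demography and genetics.

scenario_table <- function() {
  tibble::tribble(
    ~scenario, ~h2, ~frost_k, ~mortality_mode, ~differential_reproduction,
    "A", 0,   0,   "both",        TRUE,
    "B", 1,   0,   "both",        TRUE,
    "C", 1,   0,   "none",        TRUE,
    "D", 1,   0,   "both",        FALSE,
    "E", 1,   0,   "typeI_only",  TRUE,
    "F", 1,   0,   "typeII_only", TRUE,
    "G", 0.6, 0,   "both",        TRUE,
    "Ha", 1,  0.1, "both",        TRUE,
    "Hb", 1,  0.2, "both",        TRUE
  )
}

#' Scenario configuration
#'
#' Builds the full parameter set of a simulation run. The scenario letter
#' fixes the heritability, frost-damage, mortality and
#' differential-reproduction switches: A is the non-heritable neutral
#' baseline; B full adaptive evolution; C evolution without mortality; D
#' without differential reproduction; E/F with only Type I / Type II
#' mortality; G reduced heritability (h2 = 0.6); Ha/Hb moderate/strong frost
#' damage to the canopy. Any switch can still be overridden explicitly.
#'
#' @param scenario One of `"A"`, `"B"`, ..., `"Hb"`.
#' @param n_repetitions Number of replicate runs (21 in the full design).
#' @param n_generations Number of selected generations (6: G0-G5).
#' @param n_founders Founder population size (500).
#' @param n_pregenerations Neutral pre-evolution generations (5).
#' @param adult_years Years of the adult stage per generation (30); must be a
#'   multiple of the climate base period.
#' @param repro_start First adult year with reproduction (21: adults grow for
#'   20 years without reproducing, then reproduce for 10).
#' @param climate_years Length of the base climate sequence (5), looped over
#'   the adult stage.
#' @param n_loci,mu Genetic architecture (10 loci, 190 degC mean).
#' @param V_P,V_A Phenotypic variance of the control regime and additive
#'   variance used for partial heritability ((degC)^2, 22).
#' @param h2,frost_k,mortality_mode,differential_reproduction Overrides of
#'   the scenario switches.
#' @param cum_cr_crit,bb_crit Mortality thresholds (gC m-2; 45 and 160).
#' @param s_b_res,r_sp,seed_cost Seed-production parameters (100 gC m-2,
#'   0.05, 0.45 gC).
#' @param r_es,r_ss,r_sg Seed-fate rates (0.33, 0.15, 0.485).
#' @param pollen,seed Pollen and seed [dispersal_kernel()]s.
#' @param gamma_m,selfing Male-fertility exponent (0.82) and selfing rate
#'   (0.025).
#' @param k_cell Recruitment ceiling per 20 x 20 m cell (stems), standing in
#'   for seedling-stage density-dependent mortality over ages 0-39; applied
#'   by uniform subsampling before crown-overlap thinning.
#' @param seedling_survival Probability that a germination-stage seedling
#'   survives the 39-year seedling stage to be recruited at age 40; it
#'   multiplies the seed-rain intensity before the Poisson recruit draw and,
#'   like the cell ceiling, is independent of genotype.
#' @param preevo_fecundity Expected recruits per adult during neutral
#'   pre-evolution (fecundity is equal for all adults there).
#' @param climate,lapse,phenology,physiology,allometry Component parameter
#'   lists ([climate_params()], [lapse_model()], [phenology_params()],
#'   [physio_params()], [allometry_params()]); the scenario's `frost_k`
#'   overrides the phenology value.
#' @param record One of `"band"` (per-year band summaries; default) or
#'   `"tree"` (additionally keep every per-tree annual summary).
#' @return A list with class `phenoevo_config`.
#' @export
#' @examples
#' cfg <- scenario_config("B", n_repetitions = 2, n_founders = 100)
#' cfg$h2
scenario_config <- function(scenario = "B",
                            n_repetitions = 21,
                            n_generations = 6,
                            n_founders = 500,
                            n_pregenerations = 5,
                            adult_years = 30,
                            repro_start = 21,
                            climate_years = 5,
                            n_loci = 10, mu = 190,
                            V_P = 22, V_A = 22,
                            h2 = NULL, frost_k = NULL,
                            mortality_mode = NULL,
                            differential_reproduction = NULL,
                            cum_cr_crit = 45, bb_crit = 160,
                            s_b_res = 100, r_sp = 0.05, seed_cost = 0.45,
                            r_es = 0.33, r_ss = 0.15, r_sg = 0.485,
                            pollen = pollen_kernel(), seed = seed_kernel(),
                            gamma_m = 0.82, selfing = 0.025,
                            k_cell = 12,
                            seedling_survival = 0.005,
                            preevo_fecundity = 3,
                            climate = climate_params(),
                            lapse = lapse_model(),
                            phenology = phenology_params(),
                            physiology = physio_params(),
                            allometry = allometry_params(),
                            record = c("band", "tree")) {
  tab <- scenario_table()
  if (!scenario %in% tab$scenario) {
    rlang::abort(paste0("unknown scenario '", scenario, "'."))
  }
  row <- tab[tab$scenario == scenario, ]
  cfg <- as.list(environment())
  cfg$tab <- NULL
  cfg$row <- NULL
  cfg$record <- match.arg(record)
  if (is.null(cfg$h2)) cfg$h2 <- row$h2
  if (is.null(cfg$frost_k)) cfg$frost_k <- row$frost_k
  if (is.null(cfg$mortality_mode)) cfg$mortality_mode <- row$mortality_mode
  if (is.null(cfg$differential_reproduction)) {
    cfg$differential_reproduction <- row$differential_reproduction
  }
  if (cfg$adult_years %% cfg$climate_years != 0) {
    rlang::abort("`adult_years` must be a multiple of `climate_years`.")
  }
  cfg$phenology$frost_k <- cfg$frost_k
  structure(cfg, class = "phenoevo_config")
}

# Trait model implied by a configuration.
config_trait_model <- function(config) {
  trait_model(h2 = config$h2, V_P = config$V_P, V_A = config$V_A,
              mu = config$mu)
}

new_tree_cohort <- function(x, y, dbh, height, genotypes, g_value, f_crit,
                            mother = NA_integer_, father = NA_integer_,
                            id_start = 1L, allom = allometry_params()) {
  n <- length(x)
  tibble::tibble(
    id = seq.int(id_start, length.out = n),
    x = x, y = y,
    elevation = elevation_of(y),
    age = 40L,
    dbh = dbh,
    height = height,
    crown_area = crown_area_from_dbh(dbh, allom),
    genotype = asplit(genotypes, 1),
    g_value = g_value,
    f_crit = f_crit,
    mother = rep_len(mother, n),
    father = rep_len(father, n)
  )
}

genotype_matrix <- function(trees) {
  do.call(rbind, lapply(trees$genotype, as.integer))
}

#' Initialize a founder population
#'
#' Creates 500 founders (all aged 40), 100 in each of five 20-m elevational
#' bands centred on 800, 1000, 1200, 1400 and 1600 m, with uniform positions
#' within bands, Gaussian recruit sizes, Hardy-Weinberg genotypes at
#' uniformly drawn allele frequencies, and lifetime phenotypes from the
#' scenario's trait model.
#'
#' @param config A [scenario_config()].
#' @param effects Allelic effects from [draw_allelic_effects()].
#' @param seed Integer seed for the founder stream.
#' @return A simulation state: list with `trees`, `effects`, `config`,
#'   `generation` and `collapsed`, class `phenoevo_state`.
#' @export
initialize_population <- function(config, effects, seed = 1) {
  with_stream(seed, {
    n <- config$n_founders
    bands_lo <- c(790, 990, 1190, 1390, 1590) - 700
    per_band <- rep(n %/% 5, 5) + c(rep(1, n %% 5), rep(0, 5 - n %% 5))
    y <- unlist(purrr::map2(bands_lo, per_band,
                            function(lo, k) stats::runif(k, lo, lo + 20)))
    x <- stats::runif(n, 0, domain_geometry()$xmax)
    allom <- config$allometry
    dbh <- stats::rnorm(n, allom$mu_dbh, allom$sd_dbh)
    height <- stats::rnorm(n, allom$mu_h, allom$sd_h)
    founders <- init_founder_genotypes(n, config$n_loci)
    g_value <- genotypic_value(founders$genotypes, effects)
    f_crit <- phenotype_fcrit(g_value, config_trait_model(config))
    trees <- new_tree_cohort(x, y, dbh, height, founders$genotypes,
                             g_value, f_crit, allom = allom)
    structure(
      list(trees = trees, effects = effects, config = config,
           generation = 0L, next_id = n + 1L, collapsed = FALSE),
      class = "phenoevo_state"
    )
  })
}

# Father weight matrix (mothers x candidates) under reflecting borders with
# DBH-dependent male fertility; the self column is zeroed.
father_weights <- function(mother_idx, adults, kernel, gamma_m) {
  w <- reflected_kernel(adults$x, adults$y,
                        adults$x[mother_idx], adults$y[mother_idx], kernel)
  w <- sweep(w, 2, adults$dbh^gamma_m, `*`)
  w[cbind(seq_along(mother_idx), mother_idx)] <- 0
  w
}

# Create seed records for one mating episode. `fecundity` is the per-adult
# effective fecundity; seeds rain on the grid, are drawn per (cell, mother)
# as Poisson counts, positioned, and get a father, a genotype and a lifetime
# phenotype. Returns a tibble of seeds.
mate_and_disperse <- function(adults, fecundity, config, effects,
                              trait = config_trait_model(config),
                              survival = config$seedling_survival) {
  grid <- make_grid()
  mothers_idx <- which(fecundity > 0)
  if (length(mothers_idx) == 0L || nrow(adults) < 2L) {
    return(NULL)
  }
  mothers <- adults[mothers_idx, ]
  mothers$fecundity <- fecundity[mothers_idx]
  tau <- seed_rain(mothers, grid, config$seed)
  counts <- matrix(
    stats::rpois(length(tau), tau * grid$area[1] * survival),
    nrow = nrow(tau)
  )
  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    return(NULL)
  }
  k <- counts[nz]
  cell_i <- rep(nz[, 1], k)
  mother_i <- rep(mothers_idx[nz[, 2]], k)
  n_seed <- length(cell_i)

  # positions: uniform in cell, Gaussian around the mother when she is inside
  dom <- domain_geometry()
  half <- dom$cell_size / 2
  cx <- grid$cx[cell_i]
  cy <- grid$cy[cell_i]
  px <- stats::runif(n_seed, cx - half, cx + half)
  py <- stats::runif(n_seed, cy - half, cy + half)
  same <- abs(adults$x[mother_i] - cx) <= half &
    abs(adults$y[mother_i] - cy) <= half
  if (any(same)) {
    sd_pos <- config$allometry$recruit_pos_sd
    px[same] <- clamp(stats::rnorm(sum(same), adults$x[mother_i][same],
                                   sd_pos), 0, dom$xmax)
    py[same] <- clamp(stats::rnorm(sum(same), adults$y[mother_i][same],
                                   sd_pos), 0, dom$ymax)
  }

  # fathers: selfing gate, then distance- and DBH-weighted outcross draw
  u_mothers <- unique(mother_i)
  w <- father_weights(u_mothers, adults, config$pollen, config$gamma_m)
  father_i <- integer(n_seed)
  selfed <- stats::runif(n_seed) < config$selfing
  father_i[selfed] <- mother_i[selfed]
  for (r in seq_along(u_mothers)) {
    mi <- u_mothers[r]
    pick <- !selfed & mother_i == mi
    if (any(pick)) {
      father_i[pick] <- sample.int(nrow(adults), sum(pick), replace = TRUE,
                                   prob = w[r, ])
    }
  }

  geno_adults <- genotype_matrix(adults)
  child_geno <- make_gamete(geno_adults[mother_i, , drop = FALSE]) +
    make_gamete(geno_adults[father_i, , drop = FALSE])
  g_value <- genotypic_value(child_geno, effects)
  f_crit <- phenotype_fcrit(g_value, trait)
  tibble::tibble(
    cell = cell_i,
    x = px, y = py,
    mother = adults$id[mother_i],
    father = adults$id[father_i],
    genotype = asplit(child_geno, 1),
    g_value = g_value,
    f_crit = f_crit
  )
}

# Turn the dormant seed pool into an age-40 recruit cohort: per-cell ceiling
# (seedling-stage density dependence), Gaussian recruit sizes, then
# crown-overlap thinning. Both regulation steps are independent of genotype.
recruit_generation <- function(seeds, config, next_id) {
  if (is.null(seeds) || nrow(seeds) == 0L) {
    return(NULL)
  }
  keep <- unlist(lapply(split(seq_len(nrow(seeds)), seeds$cell), function(i) {
    if (length(i) > config$k_cell) sample(i, config$k_cell) else i
  }), use.names = FALSE)
  seeds <- seeds[sort(keep), ]
  allom <- config$allometry
  n <- nrow(seeds)
  dbh <- stats::rnorm(n, allom$mu_dbh, allom$sd_dbh)
  height <- stats::rnorm(n, allom$mu_h, allom$sd_h)
  trees <- new_tree_cohort(
    seeds$x, seeds$y, dbh, height,
    do.call(rbind, seeds$genotype),
    seeds$g_value, seeds$f_crit,
    mother = seeds$mother, father = seeds$father,
    id_start = next_id, allom = allom
  )
  crown_overlap_thinning(trees)
}

#' Neutral pre-evolution
#'
#' Runs generations in which mortality and fecundity are
#' genotype-independent: every adult survives to reproduce with equal
#' fecundity and the daily physiology is bypassed, but spatial mating, pollen
#' and seed dispersal operate normally, so genetic drift and restricted gene
#' flow build spatial genetic structure and among-band differentiation before
#' selection starts. Each generation the recruit cohort is thinned uniformly
#' at random back to the founder population size.
#'
#' @param state State from [initialize_population()].
#' @param n_gen Number of neutral generations (default from the config).
#' @param seed Integer seed for the pre-evolution stream.
#' @return The updated state.
#' @export
neutral_preevolution <- function(state, n_gen = NULL, seed = 1) {
  config <- state$config
  if (is.null(n_gen)) n_gen <- config$n_pregenerations
  with_stream(seed, {
    for (g in seq_len(n_gen)) {
      adults <- state$trees
      fec <- rep(config$preevo_fecundity, nrow(adults))
      # pre-evolution fecundity is already expressed as expected recruits
      seeds <- mate_and_disperse(adults, fec, config, state$effects,
                                 survival = 1)
      recruits <- recruit_generation(seeds, config, state$next_id)
      if (is.null(recruits) || nrow(recruits) == 0L) {
        state$collapsed <- TRUE
        return(state)
      }
      if (nrow(recruits) > config$n_founders) {
        recruits <- recruits[sort(sample.int(nrow(recruits),
                                             config$n_founders)), ]
      }
      state$next_id <- max(recruits$id) + 1L
      state$trees <- recruits
    }
    state
  })
}

#' Run one selected generation
#'
#' Simulates the 30-year adult stage of the current cohort under the looped
#' climate: daily physiology per tree (lapse-adjusted to each tree's
#' elevation), annual diameter growth and carbon-starvation mortality, and --
#' in the last ten adult years only -- reserve-driven seed production, spatial
#' mating and seed dispersal into a dormant pool. At the end of the stage all
#' adults are removed and the dormant pool is recruited (per-cell ceiling,
#' then crown-overlap thinning) to found the next generation at age 40.
#'
#' @param state Simulation state.
#' @param climate Base climate tibble (one `climate_years`-long block at the
#'   reference elevation); it is looped internally.
#' @return A list with the updated `state` and `records`, a list with the
#'   generation's `cohort` (trees at the first adult year), `survivors` (ids
#'   alive at the final year with their final-year summaries), `band_years`
#'   (per-year, per-band mean budburst dates and physiology), `deaths` and,
#'   when `record = "tree"`, `annual` (all per-tree annual summaries).
#' @export
run_generation <- function(state, climate) {
  config <- state$config
  trees <- state$trees
  gen <- state$generation
  if (nrow(trees) == 0L) {
    state$collapsed <- TRUE
    return(list(state = state, records = NULL))
  }
  ref_elev <- attr(climate, "reference_elevation")
  n_loops <- config$adult_years / config$climate_years
  base_years <- split(climate, climate$year)

  phys <- config$physiology
  phen <- config$phenology
  allom <- config$allometry

  alive <- rep(TRUE, nrow(trees))
  pstate <- init_physio_state(trees$dbh, trees$height, trees$crown_area,
                              phys, allom)
  cohort <- dplyr::select(trees, -"genotype")
  cohort$genotype_str <- vapply(trees$genotype,
                                function(g) paste(g, collapse = ""),
                                character(1))
  cohort$band <- bin_populations(cohort$elevation)
  seeds_pool <- list()
  band_years <- list()
  annual <- list()
  deaths <- list()
  last_summary <- NULL

  for (yr in seq_len(config$adult_years)) {
    clim_year <- base_years[[(yr - 1L) %% config$climate_years + 1L]]
    idx <- which(alive)
    if (length(idx) == 0L) break
    d_elev <- trees$elevation[idx] - ref_elev
    out <- simulate_physio_year(
      lapply(pstate, `[`, idx), clim_year,
      t_offset = config$lapse$t_slope * d_elev,
      f_crit = trees$f_crit[idx],
      phen = phen, phys = phys,
      tmin_offset = config$lapse$tmin_slope * d_elev
    )
    for (nm in names(pstate)) pstate[[nm]][idx] <- out$state[[nm]]
    summ <- out$summary
    summ$tree_id <- trees$id[idx]
    summ$year <- yr
    summ$clim_year <- (yr - 1L) %% config$climate_years + 1L

    # diameter growth from the year's wood allocation
    gr <- dbh_growth(trees$dbh[idx], trees$height[idx],
                     trees$crown_area[idx], summ$wood_alloc, allom)
    trees$dbh[idx] <- gr$dbh
    trees$height[idx] <- gr$height
    trees$crown_area[idx] <- gr$crown_area
    trees$age[idx] <- trees$age[idx] + 1L

    # reproduction in the last ten adult years, before the mortality check
    # (seed crops of trees dying this year were already shed)
    if (yr >= config$repro_start) {
      sp <- primary_seed_production(pstate$b_res[idx],
                                    trees$crown_area[idx],
                                    s_b_res = config$s_b_res,
                                    r_sp = config$r_sp,
                                    seed_cost = config$seed_cost)
      pstate$b_res[idx] <- sp$b_res
      summ$seeds <- sp$n_seeds
      summ$cum_cr <- sp$b_res  # reserves after the seed-carbon debit
      fec <- effective_fecundity(sp$n_seeds, config$r_es, config$r_ss,
                                 config$r_sg)
      if (!config$differential_reproduction) {
        fec <- rep(mean(fec), length(fec))
      }
      adults <- trees[idx, ]
      seeds <- mate_and_disperse(adults, fec, config, state$effects)
      if (!is.null(seeds)) seeds_pool[[length(seeds_pool) + 1L]] <- seeds
    } else {
      summ$seeds <- 0L
    }

    mort <- mortality_check(
      summ,
      thresholds = list(cum_cr_crit = config$cum_cr_crit,
                        bb_crit = config$bb_crit),
      mode = config$mortality_mode
    )
    died <- idx[!mort$alive]
    alive[died] <- FALSE
    if (length(died)) {
      deaths[[length(deaths) + 1L]] <- tibble::tibble(
        tree_id = trees$id[died], year = yr,
        cause = mort$cause[!mort$alive]
      )
    }

    summ$band <- cohort$band[idx]
    band_years[[yr]] <- summ |>
      dplyr::group_by(.data$band, .data$year, .data$clim_year) |>
      dplyr::summarise(
        n_trees = dplyr::n(),
        tbb = mean(.data$tbb, na.rm = TRUE),
        lgs = mean(.data$lgs),
        wsi = mean(.data$wsi),
        gpp = mean(.data$gpp),
        respiration = mean(.data$respiration),
        ring_c = mean(.data$wood_alloc),
        cum_cr = mean(.data$cum_cr),
        seeds = mean(.data$seeds),
        .groups = "drop"
      )
    if (config$record == "tree") annual[[yr]] <- summ
    last_summary <- summ
  }

  survivors <- if (is.null(last_summary)) {
    tibble::tibble()
  } else {
    dplyr::filter(last_summary, .data$tree_id %in% trees$id[alive])
  }
  records <- list(
    generation = gen,
    cohort = cohort,
    survivors = survivors,
    band_years = dplyr::bind_rows(band_years),
    deaths = dplyr::bind_rows(deaths),
    annual = if (config$record == "tree") dplyr::bind_rows(annual) else NULL
  )

  seeds_all <- dplyr::bind_rows(seeds_pool)
  recruits <- recruit_generation(seeds_all, config, state$next_id)
  if (is.null(recruits) || nrow(recruits) == 0L) {
    state$trees <- trees[0, ]
    state$collapsed <- TRUE
  } else {
    state$next_id <- max(recruits$id) + 1L
    state$trees <- recruits
  }
  state$generation <- gen + 1L
  list(state = state, records = records)
}

#' Run a full scenario
#'
#' One allelic-effects draw is shared by all repetitions; each repetition
#' draws its own founder genotypes and positions, runs the neutral
#' pre-evolution and then the selected generations G0, G1, ... under the same
#' looped synthetic climate. Every source of randomness derives from the
#' master seed through named streams, so a rerun with the same seed is
#' bit-identical.
#'
#' @param config A [scenario_config()].
#' @param seed Master seed.
#' @param climate Optional base climate tibble; generated from
#'   `config$climate` when `NULL`.
#' @return A `phenoevo_sim` object: list with `config`, `effects`, `climate`
#'   and `reps` (per-repetition generation records).
#' @export
#' @examples
#' \donttest{
#' cfg <- scenario_config("A", n_repetitions = 1, n_founders = 50,
#'                        n_generations = 2, n_pregenerations = 1,
#'                        adult_years = 5, repro_start = 1, climate_years = 5)
#' sim <- run_scenario(cfg, seed = 1)
#' }
run_scenario <- function(config, seed = 1, climate = NULL) {
  effects <- draw_allelic_effects(config$n_loci, config$mu,
                                  seed = derive_seed(seed, "effects"))
  if (is.null(climate)) {
    climate <- generate_climate(config$climate_years,
                                seed = derive_seed(seed, "climate"),
                                params = config$climate)
  }
  reps <- purrr::map(seq_len(config$n_repetitions), function(r) {
    state <- initialize_population(
      config, effects, seed = derive_seed(seed, paste0("founders", r))
    )
    state <- neutral_preevolution(
      state, seed = derive_seed(seed, paste0("preevo", r))
    )
    recs <- vector("list", config$n_generations)
    with_stream(derive_seed(seed, paste0("gens", r)), {
      for (g in seq_len(config$n_generations)) {
        if (state$collapsed) break
        out <- run_generation(state, climate)
        state <- out$state
        recs[[g]] <- out$records
      }
    })
    list(repetition = r, generations = recs[!vapply(recs, is.null, TRUE)],
         collapsed = state$collapsed)
  })
  structure(
    list(config = config, effects = effects, climate = climate, reps = reps,
         seed = seed),
    class = "phenoevo_sim"
  )
}
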