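# Configuration files (YAML, field-standard parameter names) and reproducible
# output bundles (CSV tables + JSON manifest).

config_key_map <- function() {
  # YAML key -> scenario_config argument (or nested component slot)
  tibble::tribble(
    ~key,            ~target,
    "scenario",      "scenario",
    "n_repetitions", "n_repetitions",
    "n_generations", "n_generations",
    "n_founders",    "n_founders",
    "n_pregenerations", "n_pregenerations",
    "adult_years",   "adult_years",
    "repro_start",   "repro_start",
    "climate_years", "climate_years",
    "n_loci",        "n_loci",
    "mu",            "mu",
    "V_P",           "V_P",
    "V_A",           "V_A",
    "h2",            "h2",
    "frost_k",       "frost_k",
    "mortality_mode", "mortality_mode",
    "differential_reproduction", "differential_reproduction",
    "CumCR",         "cum_cr_crit",
    "bbCR",          "bb_crit",
    "sB_res",        "s_b_res",
    "R_SP",          "r_sp",
    "c",             "seed_cost",
    "r_ES",          "r_es",
    "r_SS",          "r_ss",
    "r_SG",          "r_sg",
    "delta_S",       "seed_mean",
    "b_S",           "seed_shape",
    "delta_P",       "pollen_mean",
    "b_P",           "pollen_shape",
    "gamma_m",       "gamma_m",
    "s",             "selfing",
    "k_cell",        "k_cell",
    "s_seedling",    "seedling_survival",
    "preevo_fecundity", "preevo_fecundity",
    "SEW",           "sew",
    "T_minEffect",   "t_min_effect",
    "T2",            "t_base",
    "N_START1",      "n_start",
    "mu_H",          "mu_h",
    "SD_H",          "sd_h",
    "mu_DBH",        "mu_dbh",
    "SD_DBH",        "sd_dbh"
  )
}

#' Load a scenario configuration from a YAML file
#'
#' Keys follow the field-standard parameter names (`CumCR`, `bbCR`, `R_SP`,
#' `r_ES`, `r_SS`, `r_SG`, `delta_S`, `b_S`, `delta_P`, `b_P`, `gamma_m`,
#' `s`, `SEW`, `T_minEffect`, `mu_H`, `SD_H`, `mu_DBH`, `SD_DBH`, ...) plus
#' the scenario switches. Every key is optional (an empty file yields the full
#' default configuration); unknown keys are rejected with the offending name,
#' and basic bounds are validated.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such config file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  map <- config_key_map()
  unknown <- setdiff(names(raw), map$key)
  if (length(unknown)) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  get_raw <- function(key) raw[[key]]
  val <- function(key, default) {
    v <- get_raw(key)
    if (is.null(v)) default else v
  }
  check01 <- function(key) {
    v <- get_raw(key)
    if (!is.null(v) && (v < 0 || v > 1)) {
      rlang::abort(paste0("`", key, "` must lie in [0, 1], got ", v, "."))
    }
  }
  purrr::walk(c("h2", "frost_k", "r_ES", "r_SS", "r_SG", "s", "R_SP"),
              check01)
  for (key in c("mu", "CumCR", "bbCR", "sB_res", "c", "delta_S", "b_S",
                "delta_P", "b_P", "SEW")) {
    v <- get_raw(key)
    if (!is.null(v) && v <= 0) {
      rlang::abort(paste0("`", key, "` must be positive, got ", v, "."))
    }
  }

  phen <- phenology_params(
    t_base = val("T2", 0),
    n_start = val("N_START1", 78),
    t_min_effect = val("T_minEffect", 0)
  )
  phys <- physio_params(sew = val("SEW", 60))
  allom <- allometry_params(
    mu_h = val("mu_H", 9), sd_h = val("SD_H", 0.34),
    mu_dbh = val("mu_DBH", 13.8), sd_dbh = val("SD_DBH", 0.9)
  )
  scenario_config(
    scenario = val("scenario", "B"),
    n_repetitions = val("n_repetitions", 21),
    n_generations = val("n_generations", 6),
    n_founders = val("n_founders", 500),
    n_pregenerations = val("n_pregenerations", 5),
    adult_years = val("adult_years", 30),
    repro_start = val("repro_start", 21),
    climate_years = val("climate_years", 5),
    n_loci = val("n_loci", 10),
    mu = val("mu", 190),
    V_P = val("V_P", 22),
    V_A = val("V_A", 22),
    h2 = get_raw("h2"),
    frost_k = get_raw("frost_k"),
    mortality_mode = get_raw("mortality_mode"),
    differential_reproduction = get_raw("differential_reproduction"),
    cum_cr_crit = val("CumCR", 45),
    bb_crit = val("bbCR", 160),
    s_b_res = val("sB_res", 100),
    r_sp = val("R_SP", 0.05),
    seed_cost = val("c", 0.45),
    r_es = val("r_ES", 0.33),
    r_ss = val("r_SS", 0.15),
    r_sg = val("r_SG", 0.485),
    pollen = dispersal_kernel(val("delta_P", 37.9), val("b_P", 0.97)),
    seed = dispersal_kernel(val("delta_S", 18.13), val("b_S", 0.31)),
    gamma_m = val("gamma_m", 0.82),
    selfing = val("s", 0.025),
    k_cell = val("k_cell", 12),
    seedling_survival = val("s_seedling", 0.005),
    preevo_fecundity = val("preevo_fecundity", 3),
    phenology = phen,
    physiology = phys,
    allometry = allom
  )
}

#' Write a configuration back to YAML
#'
#' Serialises the canonical key set of [load_config()]; a load-dump-load
#' round trip reproduces the same configuration.
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  out <- list(
    scenario = config$scenario,
    n_repetitions = config$n_repetitions,
    n_generations = config$n_generations,
    n_founders = config$n_founders,
    n_pregenerations = config$n_pregenerations,
    adult_years = config$adult_years,
    repro_start = config$repro_start,
    climate_years = config$climate_years,
    n_loci = config$n_loci,
    mu = config$mu,
    V_P = config$V_P,
    V_A = config$V_A,
    h2 = config$h2,
    frost_k = config$frost_k,
    mortality_mode = config$mortality_mode,
    differential_reproduction = config$differential_reproduction,
    CumCR = config$cum_cr_crit,
    bbCR = config$bb_crit,
    sB_res = config$s_b_res,
    R_SP = config$r_sp,
    c = config$seed_cost,
    r_ES = config$r_es,
    r_SS = config$r_ss,
    r_SG = config$r_sg,
    delta_S = config$seed$mean_distance,
    b_S = config$seed$shape,
    delta_P = config$pollen$mean_distance,
    b_P = config$pollen$shape,
    gamma_m = config$gamma_m,
    s = config$selfing,
    k_cell = config$k_cell,
    s_seedling = config$seedling_survival,
    preevo_fecundity = config$preevo_fecundity,
    SEW = config$physiology$sew,
    T_minEffect = config$phenology$t_min_effect,
    T2 = config$phenology$t_base,
    N_START1 = config$phenology$n_start,
    mu_H = config$allometry$mu_h,
    SD_H = config$allometry$sd_h,
    mu_DBH = config$allometry$mu_dbh,
    SD_DBH = config$allometry$sd_dbh
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a reproducible output bundle
#'
#' Writes five files to `out_dir`: `trees.csv` (every recruited tree with
#' position, size, phenotype, genotype string, parents, survival and cause of
#' death), `annual_summary.csv` (per-tree annual physiology when the run
#' recorded it, otherwise per-band yearly means), `pedigree.csv` (id, mother,
#' father), `band_statistics.csv` (per-repetition, per-generation band
#' summaries) and `manifest.json` (configuration snapshot, master seed,
#' package version and per-repetition outcomes) from which the whole run can
#' be regenerated.
#'
#' @param sim A `phenoevo_sim`.
#' @param out_dir Output directory (created if needed).
#' @return The five file paths, invisibly.
#' @export
write_outputs <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  trees <- purrr::map_dfr(sim$reps, function(rep) {
    purrr::map_dfr(rep$generations, function(g) {
      coh <- g$cohort
      coh$repetition <- rep$repetition
      coh$generation <- g$generation
      coh$survived <- coh$id %in% g$survivors$tree_id
      if (nrow(g$deaths)) {
        coh <- dplyr::left_join(coh, g$deaths,
                                by = c(id = "tree_id"))
        coh <- dplyr::rename(coh, death_year = "year",
                             cause = "cause")
      } else {
        coh$death_year <- NA_integer_
        coh$cause <- NA_character_
      }
      coh
    })
  })
  utils::write.csv(as.data.frame(trees), p("trees.csv"), row.names = FALSE)

  annual <- purrr::map_dfr(sim$reps, function(rep) {
    purrr::map_dfr(rep$generations, function(g) {
      tab <- if (!is.null(g$annual)) g$annual else g$band_years
      dplyr::mutate(tab, repetition = rep$repetition,
                    generation = g$generation)
    })
  })
  utils::write.csv(as.data.frame(annual), p("annual_summary.csv"),
                   row.names = FALSE)

  pedigree <- dplyr::select(trees, "repetition", "generation", "id",
                            "mother", "father")
  utils::write.csv(as.data.frame(pedigree), p("pedigree.csv"),
                   row.names = FALSE)

  utils::write.csv(as.data.frame(tidy(sim)), p("band_statistics.csv"),
                   row.names = FALSE)

  cfg_path <- tempfile(fileext = ".yaml")
  dump_config(sim$config, cfg_path)
  manifest <- list(
    package = "phenoevo",
    version = as.character(utils::packageVersion("phenoevo")),
    master_seed = sim$seed,
    config = yaml::read_yaml(cfg_path),
    repetitions = purrr::map(sim$reps, function(rep) {
      gens <- rep$generations
      list(
        repetition = rep$repetition,
        collapsed = rep$collapsed,
        founder_seed = derive_seed(sim$seed,
                                   paste0("founders", rep$repetition)),
        cohort_sizes = purrr::map_int(gens, function(g) nrow(g$cohort))
      )
    })
  )
  unlink(cfg_path)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(vapply(c("trees.csv", "annual_summary.csv", "pedigree.csv",
                     "band_statistics.csv", "manifest.json"), p,
                   character(1)))
}
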