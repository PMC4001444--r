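# Post-processing: elevational band assignment, response to selection (Cb),
# selection differential (Cw), phenotypic variance and elevational shift.

#' Assign trees to elevational bands
#'
#' The 700-1700 m gradient is split into five 200-m populations Alt1-Alt5
#' with half-open intervals \[700, 900), ..., \[1500, 1700\] (the top edge is
#' closed).
#'
#' @param elevation Numeric elevations (m) in `[700, 1700]`.
#' @return A factor with levels `Alt1`..`Alt5`.
#' @export
#' @examples
#' bin_populations(c(950, 1100, 1700))  # Alt2, Alt3, Alt5
bin_populations <- function(elevation) {
  if (any(elevation < 700 | elevation > 1700)) {
    rlang::abort("elevations must lie in [700, 1700] m.")
  }
  cut(elevation,
      breaks = c(700, 900, 1100, 1300, 1500, 1700.000001),
      labels = paste0("Alt", 1:5),
      right = FALSE, include.lowest = TRUE)
}

#' Per-repetition cohort table of a simulation
#'
#' One row per tree per generation as recruited (the first adult year,
#' age 40), with its band, lifetime forcing-requirement phenotype and
#' genotypic value.
#'
#' @param sim A `phenoevo_sim` from [run_scenario()].
#' @return A tibble with columns `repetition`, `generation`, `id`, `band`,
#'   `elevation`, `f_crit`, `g_value`, `mother`, `father`.
#' @export
cohort_table <- function(sim) {
  purrr::map_dfr(sim$reps, function(rep) {
    purrr::map_dfr(rep$generations, function(g) {
      dplyr::mutate(
        dplyr::select(g$cohort, "id", "band", "elevation", "f_crit",
                      "g_value", "mother", "father"),
        generation = g$generation, repetition = rep$repetition,
        .before = 1
      )
    })
  })
}

#' Survivor table of a simulation
#'
#' Trees alive at the final adult year of each generation, with their
#' final-year physiology joined to their cohort attributes.
#'
#' @inheritParams cohort_table
#' @return A tibble like [cohort_table()] restricted to survivors.
#' @export
survivor_table <- function(sim) {
  cohorts <- cohort_table(sim)
  surv <- purrr::map_dfr(sim$reps, function(rep) {
    purrr::map_dfr(rep$generations, function(g) {
      if (is.null(g$survivors) || nrow(g$survivors) == 0L) {
        return(tibble::tibble())
      }
      tibble::tibble(repetition = rep$repetition, generation = g$generation,
                     id = g$survivors$tree_id)
    })
  })
  dplyr::inner_join(surv, cohorts,
                    by = c("repetition", "generation", "id"))
}

cb_from_deltas <- function(first, last, value_col) {
  joined <- dplyr::inner_join(
    first, last,
    by = c("repetition", "band"), suffix = c("_first", "_last")
  )
  joined |>
    dplyr::mutate(delta = .data[[paste0(value_col, "_last")]] -
                    .data[[paste0(value_col, "_first")]]) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(cb = mean(.data$delta), n_reps = dplyr::n(),
                     sd = stats::sd(.data$delta), .groups = "drop")
}

#' Response to selection of the forcing requirement (Cb)
#'
#' For each band, the change in the mean forcing requirement between the
#' first adult year (age 40) of the first and last selected generations,
#' averaged over repetitions. Repetitions where the band is empty in either
#' generation are excluded and the usable count reported. Evolution toward
#' earlier budburst yields a negative Cb.
#'
#' @param x A `phenoevo_sim` or a [cohort_table()] tibble.
#' @param value `"f_crit"` (phenotype) or `"g_value"` (genotypic value).
#' @param from,to Generation indices compared (defaults: first and last
#'   present).
#' @return A tibble with `band`, `cb` (degC), `n_reps`, `sd`.
#' @export
compute_cb_fcrit <- function(x, value = "f_crit", from = NULL, to = NULL) {
  cohorts <- if (inherits(x, "phenoevo_sim")) cohort_table(x) else x
  if (is.null(from)) from <- min(cohorts$generation)
  if (is.null(to)) to <- max(cohorts$generation)
  means <- cohorts |>
    dplyr::filter(.data$generation %in% c(from, to)) |>
    dplyr::group_by(.data$repetition, .data$generation, .data$band) |>
    dplyr::summarise(mu = mean(.data[[value]]), .groups = "drop")
  cb_from_deltas(
    dplyr::filter(means, .data$generation == from),
    dplyr::filter(means, .data$generation == to),
    "mu"
  )
}

#' Response to selection of the budburst date (Cb for TBB)
#'
#' The budburst date varies among climatic years, so the change is averaged
#' over matched climatic years: for each band and each of the base climatic
#' years, the difference between the last and first generations' mean
#' budburst dates (band means over trees and over the loops of that climatic
#' year), then averaged over climatic years and repetitions.
#'
#' @param sim A `phenoevo_sim`.
#' @param from,to Generation indices compared (defaults: first and last).
#' @return A tibble with `band`, `cb_tbb` (days), `n_reps`.
#' @export
compute_cb_tbb <- function(sim, from = NULL, to = NULL) {
  by_year <- purrr::map_dfr(sim$reps, function(rep) {
    purrr::map_dfr(rep$generations, function(g) {
      dplyr::mutate(g$band_years, generation = g$generation,
                    repetition = rep$repetition)
    })
  })
  if (is.null(from)) from <- min(by_year$generation)
  if (is.null(to)) to <- max(by_year$generation)
  means <- by_year |>
    dplyr::filter(.data$generation %in% c(from, to)) |>
    dplyr::group_by(.data$repetition, .data$generation, .data$band,
                    .data$clim_year) |>
    dplyr::summarise(tbb = mean(.data$tbb, na.rm = TRUE), .groups = "drop")
  joined <- dplyr::inner_join(
    dplyr::filter(means, .data$generation == from),
    dplyr::filter(means, .data$generation == to),
    by = c("repetition", "band", "clim_year"), suffix = c("_first", "_last")
  )
  joined |>
    dplyr::mutate(delta = .data$tbb_last - .data$tbb_first) |>
    dplyr::group_by(.data$repetition, .data$band) |>
    dplyr::summarise(delta = mean(.data$delta), .groups = "drop") |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(cb_tbb = mean(.data$delta), n_reps = dplyr::n(),
                     .groups = "drop")
}

#' Within-generation selection differential (Cw)
#'
#' The difference between the mean forcing requirement of the survivors at
#' the final adult year (age 70) and that of the full cohort at the first
#' adult year (age 40), per band, averaged over repetitions. Without
#' mortality it is exactly zero. Bands with no survivors in a repetition are
#' excluded.
#'
#' @param sim A `phenoevo_sim`.
#' @param generation Generation index (default 0).
#' @param value `"f_crit"` or `"g_value"`.
#' @return A tibble with `band`, `cw` (degC), `n_reps`.
#' @export
compute_cw <- function(sim, generation = 0, value = "f_crit") {
  cohorts <- dplyr::filter(cohort_table(sim),
                           .data$generation == !!generation)
  survivors <- dplyr::filter(survivor_table(sim),
                             .data$generation == !!generation)
  before <- cohorts |>
    dplyr::group_by(.data$repetition, .data$band) |>
    dplyr::summarise(mu = mean(.data[[value]]), .groups = "drop")
  after <- survivors |>
    dplyr::group_by(.data$repetition, .data$band) |>
    dplyr::summarise(mu = mean(.data[[value]]), .groups = "drop")
  joined <- dplyr::inner_join(before, after, by = c("repetition", "band"),
                              suffix = c("_before", "_after"))
  joined |>
    dplyr::mutate(delta = .data$mu_after - .data$mu_before) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(cw = mean(.data$delta), n_reps = dplyr::n(),
                     .groups = "drop")
}

#' Phenotypic variance of the forcing requirement per band
#'
#' Sample variance of the lifetime phenotype among the survivors at the final
#' year of the chosen generation (the last one by default), averaged over
#' repetitions; bands with fewer than two survivors are excluded. Under full
#' heritability this equals the realized additive variance.
#'
#' @param sim A `phenoevo_sim`.
#' @param generation Generation index (default: last).
#' @return A tibble with `band`, `v_p` ((degC)^2), `n_reps`.
#' @export
phenotypic_variance <- function(sim, generation = NULL) {
  survivors <- survivor_table(sim)
  if (is.null(generation)) generation <- max(survivors$generation)
  survivors |>
    dplyr::filter(.data$generation == !!generation) |>
    dplyr::group_by(.data$repetition, .data$band) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(v = stats::var(.data$f_crit), .groups = "drop") |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(v_p = mean(.data$v), n_reps = dplyr::n(),
                     .groups = "drop")
}

#' Elevational shift of the whole population
#'
#' Change in the population's mean elevation between the first and last
#' selected generations, averaged over repetitions.
#'
#' @param sim A `phenoevo_sim`.
#' @param from,to Generation indices compared (defaults: first and last).
#' @return A tibble with one row: `shift` (m) and `n_reps`.
#' @export
elevational_shift <- function(sim, from = NULL, to = NULL) {
  cohorts <- cohort_table(sim)
  if (is.null(from)) from <- min(cohorts$generation)
  if (is.null(to)) to <- max(cohorts$generation)
  means <- cohorts |>
    dplyr::filter(.data$generation %in% c(from, to)) |>
    dplyr::group_by(.data$repetition, .data$generation) |>
    dplyr::summarise(elev = mean(.data$elevation), .groups = "drop")
  joined <- dplyr::inner_join(
    dplyr::filter(means, .data$generation == from),
    dplyr::filter(means, .data$generation == to),
    by = "repetition", suffix = c("_first", "_last")
  )
  tibble::tibble(
    shift = mean(joined$elev_last - joined$elev_first),
    n_reps = nrow(joined)
  )
}
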