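# Broom-style tidiers and ggplot2 methods for simulation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into per-band, per-generation statistics
#'
#' @param x A `phenoevo_sim` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with one row per repetition x generation x band:
#'   `n_trees`, mean and variance of the forcing-requirement phenotype, mean
#'   genotypic value and mean elevation.
#' @export
tidy.phenoevo_sim <- function(x, ...) {
  cohort_table(x) |>
    dplyr::group_by(.data$repetition, .data$generation, .data$band) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      f_crit_mean = mean(.data$f_crit),
      f_crit_var = stats::var(.data$f_crit),
      g_value_mean = mean(.data$g_value),
      elevation_mean = mean(.data$elevation),
      .groups = "drop"
    ) |>
    dplyr::mutate(scenario = x$config$scenario, .before = 1)
}

#' One-row summary of a simulation
#'
#' @param x A `phenoevo_sim`.
#' @param ... Unused.
#' @return A one-row tibble: scenario switches, repetition and generation
#'   counts, number of collapsed repetitions, and the final mean population
#'   size.
#' @export
glance.phenoevo_sim <- function(x, ...) {
  final_n <- purrr::map_dbl(x$reps, function(rep) {
    gens <- rep$generations
    if (length(gens) == 0L) return(0)
    nrow(gens[[length(gens)]]$cohort)
  })
  tibble::tibble(
    scenario = x$config$scenario,
    h2 = x$config$h2,
    frost_k = x$config$frost_k,
    mortality_mode = x$config$mortality_mode,
    n_repetitions = length(x$reps),
    n_generations = max(purrr::map_int(x$reps,
                                       function(r) length(r$generations))),
    n_collapsed = sum(purrr::map_lgl(x$reps, "collapsed")),
    final_cohort_mean = mean(final_n)
  )
}

#' Plot a simulation result
#'
#' `type = "cb"` shows the per-repetition response to selection (change in
#' band mean forcing requirement between the first and last generations) as
#' boxplots per band; `type = "trait"` shows band mean trajectories of the
#' forcing requirement across generations; `type = "population"` shows band
#' population sizes across generations.
#'
#' @param object A `phenoevo_sim`.
#' @param type One of `"cb"`, `"trait"`, `"population"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenoevo_sim <- function(object, type = c("cb", "trait",
                                                   "population"), ...) {
  type <- match.arg(type)
  td <- tidy(object)
  if (type == "cb") {
    first <- min(td$generation)
    last <- max(td$generation)
    deltas <- dplyr::inner_join(
      dplyr::filter(td, .data$generation == first),
      dplyr::filter(td, .data$generation == last),
      by = c("scenario", "repetition", "band"), suffix = c("_first", "_last")
    ) |>
      dplyr::mutate(delta = .data$f_crit_mean_last -
                      .data$f_crit_mean_first)
    return(
      ggplot2::ggplot(deltas, ggplot2::aes(x = .data$band, y = .data$delta)) +
        ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
        ggplot2::geom_boxplot() +
        ggplot2::labs(
          x = "Elevational band",
          y = sprintf("Change in mean forcing requirement G%d-G%d (°C)",
                      first, last),
          title = paste("Response to selection, scenario",
                        object$config$scenario)
        )
    )
  }
  if (type == "trait") {
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$generation,
                                       y = .data$f_crit_mean,
                                       group = interaction(.data$repetition,
                                                           .data$band),
                                       colour = .data$band)) +
        ggplot2::geom_line(alpha = 0.5) +
        ggplot2::labs(x = "Generation",
                      y = "Band mean forcing requirement (°C)",
                      colour = "Band")
    )
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$generation, y = .data$n_trees,
                                   group = interaction(.data$repetition,
                                                       .data$band),
                                   colour = .data$band)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Generation", y = "Trees per band", colour = "Band")
}
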