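# Synthetic daily climate: seasonal cycle + AR(1) noise, elevational lapse,
# periodic looping across the 30-year adult phase of a generation.

#' Settings for the synthetic climate generator
#'
#' The generator emulates a Mediterranean mountain climate (north-facing beech
#' belt): a sinusoidal seasonal temperature cycle with autocorrelated daily
#' anomalies, occasional spring frost days, mostly dry summers, and one
#' anomalously hot and dry year per 5-year block (a 2003-type heatwave year).
#' All values refer to the reference elevation; other elevations are obtained
#' with [lapse_adjust()].
#'
#' @param reference_elevation Elevation (m) at which the series is generated.
#' @param t_annual_mean Annual mean of daily mean temperature (degC).
#' @param t_amplitude Half-range of the seasonal cycle (degC); the cycle peaks
#'   at `peak_doy`.
#' @param peak_doy Day of year of the warmest day of the smooth cycle.
#' @param noise_sd,noise_ar Standard deviation and lag-1 autocorrelation of the
#'   daily temperature anomaly (AR(1)).
#' @param diurnal_offset Mean difference between daily mean and daily minimum
#'   temperature (degC); the realised offset varies around it but is kept
#'   strictly positive.
#' @param n_spring_frosts Number of extra frost events injected per spring
#'   (days 90-150); each lowers that day's minimum by 2-6 degC.
#' @param wet_prob,wet_prob_summer Probability of a wet day outside/inside the
#'   summer window (days 150-250).
#' @param rain_mean Mean rainfall of a wet day (mm; exponential).
#' @param hot_year,hot_anomaly,dry_factor Index (1-based, within each 5-year
#'   block) of the heatwave year, its summer temperature anomaly (degC), and
#'   the factor applied to its summer rainfall.
#' @param rad_mean,rad_amplitude Annual mean and seasonal half-range of the
#'   daily radiation proxy (MJ m-2); wet days get 40% less.
#' @return A list of generator settings.
#' @export
climate_params <- function(reference_elevation = 1000,
                           t_annual_mean = 8,
                           t_amplitude = 9,
                           peak_doy = 202,
                           noise_sd = 2.5,
                           noise_ar = 0.7,
                           diurnal_offset = 4,
                           n_spring_frosts = 3,
                           wet_prob = 0.25,
                           wet_prob_summer = 0.12,
                           rain_mean = 6,
                           hot_year = 2,
                           hot_anomaly = 4,
                           dry_factor = 0.5,
                           rad_mean = 15,
                           rad_amplitude = 10) {
  as.list(environment())
}

#' Generate a synthetic daily climate series
#'
#' Produces `n_years` years of 365 daily records (no leap days) at the
#' generator's reference elevation. The same seed always yields the same
#' series.
#'
#' @param n_years Number of years (>= 1). The heatwave year recurs once per
#'   5-year block.
#' @param seed Integer seed for the climate stream.
#' @param params Generator settings, see [climate_params()].
#' @return A tibble with columns `year`, `doy`, `t_mean`, `t_min`, `precip`,
#'   `radiation` and attribute `reference_elevation`.
#' @export
#' @examples
#' clim <- generate_climate(n_years = 5, seed = 1)
#' dplyr::count(clim, year)
generate_climate <- function(n_years = 5, seed = 1, params = climate_params()) {
  if (!is.numeric(n_years) || length(n_years) != 1L || n_years < 1) {
    rlang::abort("`n_years` must be a positive integer.")
  }
  n_years <- as.integer(n_years)
  p <- params
  with_stream(seed, {
    years <- purrr::map(seq_len(n_years), function(yr) {
      doy <- 1:365
      smooth <- p$t_annual_mean +
        p$t_amplitude * cos(2 * pi * (doy - p$peak_doy) / 365)
      # AR(1) anomaly, stationary innovation scaling
      eps <- stats::rnorm(365, sd = p$noise_sd * sqrt(1 - p$noise_ar^2))
      anom <- as.numeric(stats::filter(eps, p$noise_ar, method = "recursive"))
      t_mean <- smooth + anom
      offset <- pmax(p$diurnal_offset + stats::rnorm(365, sd = 1), 0.5)
      t_min <- t_mean - offset

      summer <- doy >= 150 & doy <= 250
      hot <- ((yr - 1L) %% 5L) + 1L == p$hot_year
      if (hot) {
        t_mean[summer] <- t_mean[summer] + p$hot_anomaly
        t_min[summer] <- t_min[summer] + p$hot_anomaly
      }

      # extra late-frost events in the budburst window
      frost_days <- sample(90:150, p$n_spring_frosts)
      t_min[frost_days] <- pmin(t_min[frost_days], 0) -
        stats::runif(p$n_spring_frosts, 2, 6)

      wet_p <- ifelse(summer, p$wet_prob_summer, p$wet_prob)
      wet <- stats::runif(365) < wet_p
      precip <- ifelse(wet, stats::rexp(365, rate = 1 / p$rain_mean), 0)
      if (hot) precip[summer] <- precip[summer] * p$dry_factor

      radiation <- pmax(
        p$rad_mean + p$rad_amplitude * cos(2 * pi * (doy - 172) / 365) +
          stats::rnorm(365, sd = 1.5),
        0.5
      )
      radiation[wet] <- radiation[wet] * 0.6

      tibble::tibble(
        year = yr, doy = doy,
        t_mean = t_mean, t_min = t_min,
        precip = precip, radiation = radiation
      )
    })
    out <- dplyr::bind_rows(years)
    attr(out, "reference_elevation") <- p$reference_elevation
    out
  })
}

#' Linear elevational lapse model
#'
#' Each climate variable X at elevation e is `X_ref + slope_X * (e - e_ref)`.
#' Default lapse rates follow the standard environmental lapse rate of
#' -0.6 degC per 100 m for both mean and minimum temperature; precipitation and
#' radiation are left unadjusted by default.
#'
#' @param t_slope,tmin_slope Temperature lapse rates (degC m-1).
#' @param precip_slope Precipitation lapse rate (mm m-1).
#' @param radiation_slope Radiation lapse rate (MJ m-2 m-1).
#' @return A list of slopes with class `phenoevo_lapse`.
#' @export
lapse_model <- function(t_slope = -0.006, tmin_slope = -0.006,
                        precip_slope = 0, radiation_slope = 0) {
  structure(
    list(
      t_slope = t_slope, tmin_slope = tmin_slope,
      precip_slope = precip_slope, radiation_slope = radiation_slope
    ),
    class = "phenoevo_lapse"
  )
}

#' Adjust a climate series to another elevation
#'
#' Applies the linear lapse model relative to the series' reference elevation;
#' the returned series carries the new elevation as its reference, so repeated
#' adjustments compose additively. At the reference elevation the series is
#' returned unchanged.
#'
#' @param climate Climate tibble from [generate_climate()] or
#'   [read_climate_csv()].
#' @param elevation Target elevation (m).
#' @param lapse A [lapse_model()].
#' @return The adjusted climate tibble.
#' @export
lapse_adjust <- function(climate, elevation, lapse = lapse_model()) {
  ref <- attr(climate, "reference_elevation")
  if (is.null(ref)) {
    rlang::abort("`climate` has no `reference_elevation` attribute.")
  }
  d <- elevation - ref
  out <- dplyr::mutate(
    climate,
    t_mean = .data$t_mean + lapse$t_slope * d,
    t_min = .data$t_min + lapse$tmin_slope * d,
    precip = pmax(.data$precip + lapse$precip_slope * d, 0),
    radiation = pmax(.data$radiation + lapse$radiation_slope * d, 0)
  )
  attr(out, "reference_elevation") <- elevation
  out
}

#' Repeat a climate series in loops
#'
#' Concatenates `n_loops` copies of the base series with consecutive year
#' numbering, e.g. a 5-year base repeated six times drives the 30-year adult
#' stage of one generation.
#'
#' @param climate Climate tibble.
#' @param n_loops Number of repetitions (>= 1).
#' @return The looped climate tibble.
#' @export
loop_climate <- function(climate, n_loops) {
  stopifnot(n_loops >= 1)
  n_loops <- as.integer(n_loops)
  base_years <- length(unique(climate$year))
  ref <- attr(climate, "reference_elevation")
  out <- purrr::map(seq_len(n_loops) - 1L, function(k) {
    dplyr::mutate(climate, year = .data$year + k * base_years)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "reference_elevation") <- ref
  out
}

#' Read / write a climate series as CSV
#'
#' The dialect is a plain RFC-4180 CSV with columns `year`, `doy`, `t_mean`,
#' `t_min`, `precip`, `radiation`, which also allows plugging in real weather
#' station data.
#'
#' @param climate Climate tibble.
#' @param path File path.
#' @param reference_elevation Elevation (m) the file's values refer to.
#' @return `read_climate_csv()` returns a climate tibble;
#'   `write_climate_csv()` returns `path` invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(as.data.frame(climate), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path, reference_elevation = 1000) {
  df <- utils::read.csv(path)
  needed <- c("year", "doy", "t_mean", "t_min", "precip", "radiation")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    rlang::abort(paste0("climate CSV lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[needed])
  attr(out, "reference_elevation") <- reference_elevation
  out
}
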