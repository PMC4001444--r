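# Per-tree daily phenology and a surrogate carbon/water balance.
#
# Budburst follows the classical thermal-time (forcing-sum) model; the daily
# carbon balance is a deliberately simple light/temperature/drought-limited
# assimilation scheme with maintenance respiration, a reserve pool and a
# one-bucket soil water balance, delivering the quantities the demography
# consumes: budburst date (TBB), growing-season length (LGS), water stress
# index (WSI), GPP, respiration, annual wood allocation, end-of-year reserves
# (CumCR) and the pre-budburst reserve deficit.

#' Phenology parameters
#'
#' @param t_base Base temperature for forcing accumulation (degC, default 0).
#' @param n_start Day of year of rest onset: forcing accumulates from this day
#'   (default 78).
#' @param t_min_effect Frost threshold (degC, default 0): after budburst
#'   initiation, days with minimum temperature below it damage the canopy.
#' @param frost_k Fractional LAI loss per degC below the threshold (0 disables
#'   frost damage; 0.1 and 0.2 are the moderate/strong frost regimes).
#' @return A list of phenology settings.
#' @export
phenology_params <- function(t_base = 0, n_start = 78, t_min_effect = 0,
                             frost_k = 0) {
  stopifnot(frost_k >= 0, frost_k <= 1)
  as.list(environment())
}

#' Surrogate carbon/water balance parameters
#'
#' Calibrated so that a mid-gradient tree assimilates on the order of
#' 10^3 gC m-2 yr-1 with respiration and leaf-construction costs leaving a
#' positive but climate-sensitive reserve margin.
#'
#' @param a_max Maximum daily assimilation (gC m-2 crown d-1).
#' @param k_beer Beer-Lambert light-extinction coefficient on LAI.
#' @param t_opt,t_width Optimum (degC) and width (degC) of the parabolic
#'   temperature response of assimilation.
#' @param r0,r_m Baseline (gC m-2 d-1) and biomass-proportional (d-1)
#'   maintenance-respiration coefficients at 15 degC.
#' @param q10 Temperature sensitivity of respiration.
#' @param lai_max Canopy leaf area index set at budburst (m2 m-2).
#' @param lma Leaf mass per area (g dry mass m-2, default 93).
#' @param carbon_frac Carbon fraction of dry mass.
#' @param growth_resp Growth-respiration overhead on leaf construction (0.5 =
#'   50% extra carbon respired while building leaves).
#' @param senescence_doy Fixed day of leaf fall (default 285).
#' @param sew Soil extractable water (mm, default 60).
#' @param drought_threshold Relative soil water content below which
#'   assimilation is reduced (default 0.4).
#' @param et_coef Evapotranspiration per unit LAI per degC (mm).
#' @param f_wood Fraction of positive daily net carbon allocated to wood (the
#'   rest goes to reserves).
#' @param init_reserves Reserve pool of a newly created tree (gC m-2).
#' @return A list of physiology settings.
#' @export
physio_params <- function(a_max = 14, k_beer = 0.5, t_opt = 20, t_width = 18,
                          r0 = 0.35, r_m = 2e-4, q10 = 2,
                          lai_max = 5, lma = 93, carbon_frac = 0.5,
                          growth_resp = 0.5, senescence_doy = 285,
                          sew = 60, drought_threshold = 0.4, et_coef = 0.02,
                          f_wood = 0.35, init_reserves = 400) {
  as.list(environment())
}

#' Thermal-time budburst date
#'
#' Daily forcing is `max(t_mean - t_base, 0)` from the rest-onset day onwards
#' (the onset day included); its cumulative sum is the state of forcing, and
#' budburst occurs on the first day the state reaches the tree's critical
#' forcing requirement (ties at exact equality count as budburst). A
#' non-positive requirement degenerates to budburst on the rest-onset day.
#'
#' @param t_mean Daily mean temperatures for one year (length >= 365 used as
#'   days 1..365), or a matrix with one column per tree.
#' @param f_crit Critical forcing requirement(s) (degC); recycled against the
#'   columns of `t_mean`.
#' @param params [phenology_params()].
#' @return Integer vector of budburst days of year (`NA` when the requirement
#'   is never met).
#' @export
#' @examples
#' budburst_date(rep(10, 365), f_crit = 190)  # 19 forcing days from day 78
budburst_date <- function(t_mean, f_crit, params = phenology_params()) {
  if (is.null(dim(t_mean))) t_mean <- matrix(t_mean, ncol = 1)
  t_mean <- t_mean[1:365, , drop = FALSE]
  if (ncol(t_mean) == 1L && length(f_crit) > 1L) {
    t_mean <- t_mean[, rep(1L, length(f_crit)), drop = FALSE]
  }
  forcing <- pmax(t_mean - params$t_base, 0)
  forcing[seq_len(params$n_start - 1L), ] <- 0
  s <- apply(forcing, 2, cumsum)
  tbb <- vapply(seq_along(f_crit), function(j) {
    # first day with state >= requirement; 0/negative requirement -> onset day
    idx <- findInterval(f_crit[j], s[, j], left.open = TRUE) + 1L
    if (idx > 365L) NA_integer_ else as.integer(max(idx, params$n_start))
  }, integer(1))
  tbb
}

#' Frost damage to the canopy
#'
#' On a post-budburst day whose minimum temperature falls below the frost
#' threshold, LAI is reduced multiplicatively by `frost_k` per degC below the
#' threshold, clamped at total canopy loss.
#'
#' @param lai Current leaf area index (vectorised).
#' @param t_min Daily minimum temperature (degC).
#' @param params [phenology_params()].
#' @return Damaged LAI.
#' @export
#' @examples
#' frost_damage(5, t_min = -2, phenology_params(frost_k = 0.1))  # 4.0
frost_damage <- function(lai, t_min, params = phenology_params()) {
  factor <- pmax(0, 1 - params$frost_k * pmax(0, params$t_min_effect - t_min))
  lai * factor
}

#' Initial physiological state for a cohort of trees
#'
#' @param dbh,height,crown_area Tree dimensions (cm, m, m2).
#' @param phys [physio_params()].
#' @param allom [allometry_params()].
#' @return A list of per-tree numeric vectors: `b_tree` (structural biomass,
#'   gC m-2 crown), `b_res` (reserves, gC m-2), `soil_water` (mm).
#' @export
init_physio_state <- function(dbh, height, crown_area,
                              phys = physio_params(),
                              allom = allometry_params()) {
  list(
    b_tree = stem_carbon(dbh, height, allom) / crown_area,
    b_res = rep(phys$init_reserves, length(dbh)),
    soil_water = rep(phys$sew, length(dbh))
  )
}

#' Simulate one physiological year for a cohort of trees
#'
#' Runs the daily surrogate balance for days 1..365. Before budburst,
#' maintenance respiration drains the reserve pool (then structural biomass if
#' reserves are exhausted). At budburst the leaf-construction cost (leaf
#' carbon plus growth-respiration overhead) is drawn from reserves and the
#' canopy is set to `lai_max`; the shortfall, if any, is the pre-budburst
#' reserve deficit used by the Type II mortality rule. During the leaf period
#' assimilation is light-, temperature- and drought-limited; the daily
#' fractional drought reduction accumulates into the water stress index.
#' Positive net carbon is split between wood and reserves; leaves fall on the
#' fixed senescence day. Each tree has its own one-bucket soil water balance.
#'
#' @param state State list from [init_physio_state()] (or a previous year).
#' @param climate_year Climate tibble rows for one year (365 days) at the
#'   reference elevation.
#' @param t_offset Per-tree temperature offset (degC) from the lapse model,
#'   `slope * (elevation - reference)`, applied to the daily mean temperature.
#' @param tmin_offset Offset applied to the daily minimum temperature
#'   (defaults to `t_offset`).
#' @param f_crit Per-tree critical forcing requirement (degC).
#' @param phen [phenology_params()].
#' @param phys [physio_params()].
#' @return A list with `state` (updated pools) and `summary`, a tibble with
#'   one row per tree: `tbb`, `lgs`, `wsi`, `gpp`, `respiration`,
#'   `wood_alloc`, `cum_cr`, `bb_deficit`, `litter`, `unmet_resp` and the
#'   start/end values of both carbon pools (for carbon-balance audits).
#' @export
simulate_physio_year <- function(state, climate_year, t_offset, f_crit,
                                 phen = phenology_params(),
                                 phys = physio_params(),
                                 tmin_offset = t_offset) {
  n <- length(f_crit)
  stopifnot(nrow(climate_year) >= 365, length(t_offset) %in% c(1L, n))
  if (length(t_offset) == 1L) t_offset <- rep(t_offset, n)
  if (length(tmin_offset) == 1L) tmin_offset <- rep(tmin_offset, n)
  t_base_mean <- climate_year$t_mean[1:365]
  t_base_min <- climate_year$t_min[1:365]
  precip <- climate_year$precip[1:365]

  tbb <- budburst_date(outer(t_base_mean, t_offset, `+`), f_crit, phen)

  b_tree <- state$b_tree
  b_res <- state$b_res
  soil <- state$soil_water
  b_tree0 <- b_tree
  b_res0 <- b_res

  lai <- numeric(n)
  leaf_pool <- numeric(n)
  wsi <- numeric(n)
  gpp <- numeric(n)
  resp <- numeric(n)
  wood <- numeric(n)
  litter <- numeric(n)
  unmet <- numeric(n)
  bb_deficit <- numeric(n)

  leaf_c_full <- phys$lai_max * phys$lma * phys$carbon_frac

  for (d in 1:365) {
    tm <- t_base_mean[d] + t_offset
    tn <- t_base_min[d] + tmin_offset

    # a requirement met only at/after the senescence day develops no canopy
    flush <- !is.na(tbb) & tbb == d & d < phys$senescence_doy
    if (any(flush)) {
      cost <- leaf_c_full * (1 + phys$growth_resp)
      bb_deficit[flush] <- pmax(0, cost - b_res[flush])
      pay <- pmin(b_res[flush], cost)
      b_res[flush] <- b_res[flush] - pay
      b_tree[flush] <- pmax(b_tree[flush] - (cost - pay), 0)
      resp[flush] <- resp[flush] + leaf_c_full * phys$growth_resp
      leaf_pool[flush] <- leaf_c_full
      lai[flush] <- phys$lai_max
    }

    leafy <- lai > 0
    if (phen$frost_k > 0 && any(leafy)) {
      new_lai <- frost_damage(lai[leafy], tn[leafy], phen)
      lost <- (lai[leafy] - new_lai) / phys$lai_max * leaf_c_full
      litter[leafy] <- litter[leafy] + lost
      leaf_pool[leafy] <- leaf_pool[leafy] - lost
      lai[leafy] <- new_lai
      leafy <- lai > 0
    }

    r_day <- (phys$r0 + phys$r_m * b_tree) * phys$q10^((tm - 15) / 10)
    resp <- resp + r_day

    a_day <- numeric(n)
    if (d < phys$senescence_doy && any(leafy)) {
      rel <- soil / phys$sew
      dmod <- pmin(1, rel / phys$drought_threshold)
      tmod <- pmax(0, 1 - ((tm - phys$t_opt) / phys$t_width)^2)
      a <- phys$a_max * (1 - exp(-phys$k_beer * lai)) * tmod * dmod
      a_day[leafy] <- a[leafy]
      wsi[leafy] <- wsi[leafy] + (1 - dmod[leafy])
      gpp <- gpp + a_day
    }

    net <- a_day - r_day
    pos <- net > 0
    wood[pos] <- wood[pos] + phys$f_wood * net[pos]
    b_tree[pos] <- b_tree[pos] + phys$f_wood * net[pos]
    b_res[pos] <- b_res[pos] + (1 - phys$f_wood) * net[pos]
    if (any(!pos)) {
      draw <- -net[!pos]
      from_res <- pmin(b_res[!pos], draw)
      b_res[!pos] <- b_res[!pos] - from_res
      rem <- draw - from_res
      from_tree <- pmin(b_tree[!pos], rem)
      b_tree[!pos] <- b_tree[!pos] - from_tree
      unmet[!pos] <- unmet[!pos] + (rem - from_tree)
    }

    if (d == phys$senescence_doy) {
      litter <- litter + leaf_pool
      leaf_pool <- numeric(n)
      lai <- numeric(n)
    }

    et <- (phys$et_coef * lai + 0.01) * pmax(tm, 0)
    soil <- clamp(soil + precip[d] - et, 0, phys$sew)
  }

  summary <- tibble::tibble(
    tbb = tbb,
    lgs = ifelse(is.na(tbb), 0, pmax(phys$senescence_doy - tbb, 0)),
    wsi = wsi,
    gpp = gpp,
    respiration = resp,
    wood_alloc = wood,
    cum_cr = b_res,
    bb_deficit = bb_deficit,
    litter = litter,
    unmet_resp = unmet,
    b_tree_start = b_tree0, b_tree_end = b_tree,
    b_res_start = b_res0, b_res_end = b_res
  )
  list(
    state = list(b_tree = b_tree, b_res = b_res, soil_water = soil),
    summary = summary
  )
}
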