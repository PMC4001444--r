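test_that("budburst date matches hand-computed forcing sums", {
  # constant 10 degC: 19 forcing days from day 78 -> budburst on day 96
  expect_equal(budburst_date(rep(10, 365), f_crit = 190), 96L)
  # zero requirement degenerates to the rest-onset day
  expect_equal(budburst_date(rep(10, 365), f_crit = 0), 78L)
  # never enough forcing
  expect_true(is.na(budburst_date(rep(-5, 365), f_crit = 190)))
})

test_that("budburst date equals the brute-force cumulative-sum oracle", {
  oracle <- function(t_mean, f_crit, t_base = 0, n_start = 78) {
    s <- 0
    for (d in 1:365) {
      if (d >= n_start) s <- s + max(t_mean[d] - t_base, 0)
      if (s >= f_crit) return(d)
    }
    NA_integer_
  }
  withr::with_seed(42, {
    for (k in 1:100) {
      temps <- stats::rnorm(365, mean = 8 + 9 * cos(2 * pi * (1:365 - 202) /
                                                      365), sd = 3)
      f <- stats::runif(1, 50, 400)
      expect_identical(budburst_date(temps, f), as.integer(oracle(temps, f)))
    }
  })
})

test_that("budburst responds monotonically to warming and to the requirement", {
  withr::with_seed(1, {
    temps <- stats::rnorm(365, 8, 4)
    t1 <- budburst_date(temps, 190)
    expect_lte(budburst_date(temps + 2, 190), t1)
    expect_gte(budburst_date(temps, 250), t1)
  })
})

test_that("frost damage reduces LAI per degree below the threshold", {
  p <- phenology_params(frost_k = 0.1)
  expect_equal(frost_damage(5, t_min = -2, p), 4)
  expect_equal(frost_damage(5, t_min = 1, p), 5)
  # strong frost clamps at total canopy loss
  expect_equal(frost_damage(5, t_min = -6, phenology_params(frost_k = 0.2)),
               0)
  # disabled frost leaves any LAI unchanged
  expect_equal(frost_damage(3.2, t_min = -10, phenology_params(frost_k = 0)),
               3.2)
})

test_that("a tree that never flushes assimilates nothing and drains reserves", {
  clim <- flat_climate(t_mean = 5)
  st <- init_physio_state(13.8, 9, crown_area_from_dbh(13.8))
  out <- simulate_physio_year(st, clim, t_offset = 0, f_crit = 1e6)
  s <- out$summary
  expect_true(is.na(s$tbb))
  expect_equal(s$gpp, 0)
  expect_equal(s$bb_deficit, 0)
  expect_lt(s$b_res_end, s$b_res_start)
  # bookkeeping identity: reserves fall by exactly the respiration paid
  expect_equal(s$b_res_start - s$b_res_end + s$b_tree_start - s$b_tree_end,
               s$respiration, tolerance = 1e-9)
})

test_that("the drought modifier shortfall accumulates into the WSI", {
  # one leafy day at relative soil water 0.2 -> modifier 0.5, WSI = 0.5
  clim <- flat_climate(t_mean = 10, precip = 0)
  clim$precip <- 0.1  # exactly balances the leafless evapotranspiration
  st <- list(b_tree = 1500, b_res = 500, soil_water = 12)
  phys <- physio_params(senescence_doy = 79)
  out <- simulate_physio_year(st, clim, 0, f_crit = 0, phys = phys)
  expect_equal(out$summary$tbb, 78L)
  expect_equal(out$summary$wsi, 0.5)
})

test_that("WSI is zero in a year with ample soil water", {
  clim <- flat_climate(t_mean = 12, precip = 5)
  st <- init_physio_state(13.8, 9, crown_area_from_dbh(13.8))
  out <- simulate_physio_year(st, clim, 0, f_crit = 150)
  expect_equal(out$summary$wsi, 0)
  expect_gt(out$summary$gpp, 0)
})

test_that("carbon is conserved over full years across the gradient", {
  clim <- generate_climate(2, seed = 11)
  years <- split(clim, clim$year)
  elevs <- c(700, 1200, 1700)
  off <- -0.006 * (elevs - 1000)
  st <- init_physio_state(rep(13.8, 3), rep(9, 3),
                          rep(crown_area_from_dbh(13.8), 3))
  for (y in years) {
    out <- simulate_physio_year(st, y, off, f_crit = c(150, 190, 230))
    s <- out$summary
    resid <- (s$b_tree_end - s$b_tree_start) + (s$b_res_end - s$b_res_start) -
      (s$gpp - s$respiration - s$litter + s$unmet_resp)
    expect_lt(max(abs(resid)) / max(s$gpp), 1e-9)
    st <- out$state
  }
})

test_that("growing seasons shorten with elevation", {
  clim <- generate_climate(1, seed = 12)
  st <- init_physio_state(rep(13.8, 2), rep(9, 2),
                          rep(crown_area_from_dbh(13.8), 2))
  out <- simulate_physio_year(st, clim, t_offset = c(0, -0.006 * 600),
                              f_crit = c(190, 190))
  expect_lt(out$summary$lgs[2], out$summary$lgs[1])
})

test_that("disabled frost makes minimum temperature irrelevant", {
  clim <- generate_climate(1, seed = 13)
  colder <- dplyr::mutate(clim, t_min = t_min - 10)
  attr(colder, "reference_elevation") <- 1000
  st <- init_physio_state(13.8, 9, crown_area_from_dbh(13.8))
  a <- simulate_physio_year(st, clim, 0, 190,
                            phen = phenology_params(frost_k = 0))
  b <- simulate_physio_year(st, colder, 0, 190,
                            phen = phenology_params(frost_k = 0))
  expect_identical(a$summary, b$summary)
})

test_that("late frosts with damage enabled reduce canopy and assimilation", {
  clim <- flat_climate(t_mean = 10, t_min = 8)
  clim$t_min[100:102] <- -3  # three post-budburst frost nights
  st <- init_physio_state(13.8, 9, crown_area_from_dbh(13.8))
  undamaged <- simulate_physio_year(st, clim, 0, 190,
                                    phen = phenology_params(frost_k = 0))
  damaged <- simulate_physio_year(st, clim, 0, 190,
                                  phen = phenology_params(frost_k = 0.2))
  expect_lt(damaged$summary$gpp, undamaged$summary$gpp)
  expect_gt(damaged$summary$litter, 0)
})
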