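test_that("mortality thresholds and mode masking behave as specified", {
  s <- function(cum, bbd) tibble::tibble(cum_cr = cum, bb_deficit = bbd)
  expect_equal(mortality_check(s(44, 0))$cause, "typeI")
  expect_false(mortality_check(s(44, 0))$alive)
  expect_equal(mortality_check(s(100, 161))$cause, "typeII")
  expect_true(mortality_check(s(100, 161), mode = "typeI_only")$alive)
  expect_true(mortality_check(s(44, 161), mode = "typeII_only")$alive ==
                FALSE)
  expect_equal(mortality_check(s(44, 161), mode = "typeII_only")$cause,
               "typeII")
  expect_true(mortality_check(s(100, 0))$alive)
  expect_true(all(mortality_check(s(44, 200), mode = "none")$alive))

  # the two causes partition the dead: never both, never neither when dead
  chk <- mortality_check(s(c(44, 100, 44, 100), c(200, 200, 0, 0)))
  expect_equal(chk$cause, c("typeI", "typeII", "typeI", "none"))
  expect_equal(chk$alive, chk$cause == "none")
})

test_that("seed production requires reserves above the critical level", {
  expect_equal(primary_seed_production(90, crown_area = 10)$n_seeds, 0L)
  out <- primary_seed_production(200, crown_area = 10)
  expect_equal(out$n_seeds, 222L)  # floor(0.05 * 200 * 10 / 0.45)
  expect_equal(out$b_res, 200 - 0.05 * 200)
  expect_equal(primary_seed_production(200, crown_area = 0)$n_seeds, 0L)
})

test_that("effective fecundity discounts the seed crop by the seed fates", {
  expect_equal(effective_fecundity(1000), 1000 * 0.67 * 0.15 * 0.485)
  expect_equal(effective_fecundity(0), 0)
  expect_equal(effective_fecundity(1000, r_es = 1), 0)
  expect_error(effective_fecundity(10, r_ss = 1.5), "\\[0, 1\\]")
})

test_that("the exponential-power kernel reduces to the exponential at b = 1", {
  k <- dispersal_kernel(mean_distance = 30, shape = 1)
  expect_equal(k$scale, 15)  # delta = 2a
  withr::with_seed(1, {
    d <- sample_kernel_distance(2e5, k)
    expect_equal(mean(d), 30, tolerance = 0.01)
  })
})

test_that("kernel density is a proper density and decays with distance", {
  for (k in list(pollen_kernel(), seed_kernel())) {
    mass <- stats::integrate(function(r) 2 * pi * r * kernel_density(r, k),
                             0, Inf, rel.tol = 1e-8)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    r <- c(1, 5, 20, 80)
    expect_true(all(diff(kernel_density(r, k)) < 0))
  }
  expect_error(kernel_density(-1, pollen_kernel()), "non-negative")
})

test_that("sampled dispersal distances recover the configured means", {
  withr::with_seed(2, {
    dp <- sample_kernel_distance(2e5, pollen_kernel())
    ds <- sample_kernel_distance(2e5, seed_kernel())
  })
  expect_equal(mean(dp), 37.9, tolerance = 0.01)
  expect_equal(mean(ds), 18.13, tolerance = 0.02)
})

test_that("pollen contributions respect symmetry and male fertility", {
  mother <- tibble::tibble(id = 1L, x = 100, y = 500)
  cands <- tibble::tibble(id = 1:3, x = c(100, 90, 110), y = 500,
                          dbh = c(20, 30, 30))
  pc <- pollen_contributions(mother, cands)
  expect_equal(nrow(pc), 2L)        # the mother is excluded
  expect_equal(sum(pc$prob), 1)
  expect_equal(pc$prob[1], 0.5, tolerance = 1e-3)  # symmetric candidates

  # equal distance, DBH 40 vs 20 -> weight ratio 2^0.82
  cands2 <- tibble::tibble(id = 1:3, x = c(100, 90, 110), y = 500,
                           dbh = c(20, 40, 20))
  pc2 <- pollen_contributions(mother, cands2)
  expect_equal(pc2$prob[pc2$id == 2] / pc2$prob[pc2$id == 3], 2^0.82,
               tolerance = 0.01)
  expect_error(pollen_contributions(mother, cands[1, ]), "candidates")
})

test_that("selfing occurs at the configured rate", {
  mother <- tibble::tibble(id = 1L, x = 100, y = 500)
  cands <- tibble::tibble(id = 1:20, x = stats::runif(20, 0, 200),
                          y = stats::runif(20, 400, 600), dbh = 20)
  withr::with_seed(3, {
    dads <- sample_father(mother, cands, n = 1e5)
  })
  frac <- mean(dads == 1L)
  expect_lt(abs(frac - 0.025), 3 * sqrt(0.025 * 0.975 / 1e5))
})

test_that("the grid covers the domain with 500 square cells", {
  g <- make_grid()
  expect_equal(nrow(g), 500)
  expect_true(all(g$area == 400))
  expect_equal(range(g$cx), c(10, 190))
  expect_equal(range(g$cy), c(10, 990))
})

test_that("seed rain scales with fecundity and conserves seed numbers", {
  g <- make_grid()
  mothers <- tibble::tibble(x = 100, y = 500, fecundity = 0)
  expect_true(all(seed_rain(mothers, g) == 0))

  # with a smooth kernel and reflecting borders the discretized rain sums to
  # the fecundity (first-order mirrors miss only the corner-diagonal mass)
  mothers$fecundity <- 100
  tau <- seed_rain(mothers, g, dispersal_kernel(30, 1))
  expect_equal(sum(tau * g$area), 100, tolerance = 0.05)

  # intensity decreases along a row of cells away from the mother
  row_cells <- g[abs(g$cy - 490) < 1e-9 & g$cx >= 100, ]
  tau_row <- seed_rain(mothers, g, dispersal_kernel(30, 1))[row_cells$cell]
  expect_true(all(diff(tau_row) < 0))
})

test_that("recruits are placed uniformly unless the mother is in the cell", {
  g <- make_grid()
  cell <- g[g$cx == 110 & g$cy == 510, ]
  far_mother <- tibble::tibble(x = 30, y = 900)
  withr::with_seed(4, {
    pos <- place_recruit(5000, cell, far_mother)
  })
  expect_true(all(pos$x >= 100 & pos$x <= 120))
  expect_true(all(pos$y >= 500 & pos$y <= 520))
  ks <- stats::ks.test((pos$x - 100) / 20, "punif")
  expect_gt(ks$p.value, 0.001)

  near_mother <- tibble::tibble(x = 110, y = 510)
  withr::with_seed(5, {
    pos2 <- place_recruit(5000, cell, near_mother)
  })
  expect_equal(mean(pos2$x), 110, tolerance = 0.3)
  expect_equal(mean(pos2$y), 510, tolerance = 0.3)
  expect_gt(stats::sd(pos2$x), 2)  # Gaussian spread, not uniform-in-cell
  dom <- domain_geometry()
  expect_true(all(pos2$x >= 0 & pos2$x <= dom$xmax))
})

test_that("crown thinning removes all pairs above the overlap limit", {
  # two coincident equal crowns: exactly one survives
  two <- tibble::tibble(x = c(50, 50), y = c(50, 50), crown_area = 10)
  withr::with_seed(6, {
    expect_equal(nrow(crown_overlap_thinning(two)), 1L)
  })

  # well-separated trees all survive
  apart <- tibble::tibble(x = c(10, 50, 90), y = 10, crown_area = 10)
  expect_equal(nrow(crown_overlap_thinning(apart)), 3L)

  # dense random stand: audit survivors with an independent lens-area oracle
  lens_area <- function(d, r1, r2) {
    if (d >= r1 + r2) return(0)
    if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
    r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
      r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
      0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) *
                   (d + r1 + r2))
  }
  withr::with_seed(7, {
    stand <- tibble::tibble(
      x = stats::runif(150, 0, 40), y = stats::runif(150, 0, 40),
      crown_area = stats::runif(150, 5, 20)
    )
    kept <- crown_overlap_thinning(stand)
  })
  expect_lt(nrow(kept), nrow(stand))
  r <- sqrt(kept$crown_area / pi)
  for (i in seq_len(nrow(kept) - 1)) {
    for (j in (i + 1):nrow(kept)) {
      d <- sqrt((kept$x[i] - kept$x[j])^2 + (kept$y[i] - kept$y[j])^2)
      frac <- lens_area(d, r[i], r[j]) / (pi * min(r[i], r[j])^2)
      expect_lte(frac, 0.30 + 1e-9)
    }
  }
})

test_that("diameter growth inverts the stem allometry sensibly", {
  g0 <- dbh_growth(13.8, 9, 11.7, wood_alloc = 0)
  expect_equal(g0$dbh, 13.8)
  g1 <- dbh_growth(13.8, 9, 11.7, wood_alloc = 200)
  g2 <- dbh_growth(13.8, 9, 11.7, wood_alloc = 400)
  expect_gt(g1$dbh, 13.8)
  expect_gt(g1$height, 9 * 0.999)
  # concave inversion: doubling the carbon less than doubles the increment
  expect_lt(g2$dbh - 13.8, 2 * (g1$dbh - 13.8))
})
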