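test_that("allelic effects have equal midpoints and bounded effects", {
  eff <- draw_allelic_effects(n_loci = 10, mu = 190, seed = 1)
  expect_equal(eff$m, rep(19, 10))
  expect_true(all(eff$alpha >= 0 & eff$alpha <= 19))
  expect_identical(eff, draw_allelic_effects(10, 190, seed = 1))
  expect_error(draw_allelic_effects(10, mu = -1), "positive")
})

test_that("allelic effects average mu / (2 n_loci) across draws", {
  alphas <- unlist(lapply(1:2000, function(s) {
    draw_allelic_effects(10, 190, seed = s)$alpha
  }))
  se <- stats::sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 9.5), 3 * se + 0.05)
})

test_that("founder genotypes follow Hardy-Weinberg at the given frequencies", {
  fixed <- init_founder_genotypes(50, n_loci = 3, seed = 1, freqs = c(1, 1, 1))
  expect_true(all(fixed$genotypes == 2L))

  half <- init_founder_genotypes(1e5, n_loci = 1, seed = 2, freqs = 0.5)
  het <- mean(half$genotypes[, 1] == 1L)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("founder genotypic values average the configured trait mean", {
  eff <- draw_allelic_effects(seed = 3)
  means <- vapply(1:50, function(s) {
    g <- init_founder_genotypes(200, seed = s)$genotypes
    mean(genotypic_value(g, eff))
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 190), 3 * se + 0.5)
})

test_that("genotypic value is the additive sum over loci", {
  eff <- draw_allelic_effects(seed = 4)
  het <- rep(1L, 10)
  expect_equal(genotypic_value(het, eff), 190)
  expect_equal(genotypic_value(rep(2L, 10), eff), 190 + sum(eff$alpha))
  expect_equal(genotypic_value(rep(0L, 10), eff), 190 - sum(eff$alpha))
  expect_error(genotypic_value(rep(1L, 9), eff), "loci")

  # exact linearity in allele counts
  g1 <- c(2L, 0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 1L)
  g2 <- c(0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L, 1L)
  expect_equal(
    genotypic_value(g1, eff) + genotypic_value(g2, eff),
    2 * genotypic_value(het, eff) +
      sum(eff$alpha * (g1 - 1)) + sum(eff$alpha * (g2 - 1))
  )
})

test_that("trait model handles the three heritability regimes", {
  expect_equal(trait_model(h2 = 0)$mode, "control")
  expect_equal(trait_model(h2 = 1)$mode, "heritable")
  expect_equal(trait_model(h2 = 0.6)$mode, "partial")
  expect_equal(trait_model(h2 = 0.6)$V_E, 22 * 0.4 / 0.6)
  expect_error(trait_model(h2 = 1.5), "\\[0, 1\\]")

  expect_equal(phenotype_fcrit(195, trait_model(h2 = 1)), 195)

  set.seed(1)
  ctrl <- phenotype_fcrit(rep(0, 1e5), trait_model(h2 = 0, V_P = 22))
  se <- 22 * sqrt(2 / 1e5)
  expect_lt(abs(stats::var(ctrl) - 22), 3 * se)
  expect_lt(abs(mean(ctrl) - 190), 3 * sqrt(22 / 1e5))

  set.seed(2)
  part <- phenotype_fcrit(rep(100, 1e5), trait_model(h2 = 0.6))
  v_e <- 22 * 0.4 / 0.6
  expect_lt(abs(stats::var(part - 100) - v_e), 3 * v_e * sqrt(2 / 1e5))
})

test_that("gametes segregate fairly and without mutation", {
  hom <- matrix(c(2L, 0L, 2L, 0L), nrow = 1)
  set.seed(1)
  expect_equal(make_gamete(hom), matrix(c(1L, 0L, 1L, 0L), nrow = 1))
  # selfing a fully homozygous parent recreates the parent
  expect_equal(make_gamete(hom) + make_gamete(hom), hom)

  het <- matrix(1L, nrow = 1e5, ncol = 1)
  set.seed(2)
  frac <- mean(make_gamete(het))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("additive variance matches the Monte-Carlo genotype variance", {
  eff <- draw_allelic_effects(seed = 5)
  expect_equal(additive_variance(rep(0, 10), eff), 0)
  expect_equal(additive_variance(rep(1, 10), eff), 0)
  unit_eff <- tibble::tibble(locus = 1:10, m = 19, alpha = 1)
  expect_equal(additive_variance(rep(0.5, 10), unit_eff), 5)
  expect_error(additive_variance(rep(1.5, 10), eff), "\\[0, 1\\]")

  p <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.6, 0.8, 0.5)
  g <- init_founder_genotypes(1e5, seed = 6, freqs = p)$genotypes
  v_mc <- stats::var(genotypic_value(g, eff))
  v_th <- additive_variance(p, eff)
  expect_lt(abs(v_mc - v_th), 3 * v_th * sqrt(2 / 1e5) + 0.05)
})

test_that("offspring on mid-parent regression recovers full heritability", {
  eff <- draw_allelic_effects(seed = 7)
  parents <- init_founder_genotypes(4000, seed = 8)$genotypes
  dads <- parents[sample.int(4000), ]
  set.seed(9)
  kids <- make_gamete(parents) + make_gamete(dads)
  midparent <- (genotypic_value(parents, eff) +
                  genotypic_value(dads, eff)) / 2
  slope <- stats::coef(stats::lm(genotypic_value(kids, eff) ~ midparent))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("gamete formation preserves allele frequencies in expectation", {
  p <- c(0.2, 0.5, 0.8)
  g <- init_founder_genotypes(2e4, n_loci = 3, seed = 10, freqs = p)$genotypes
  set.seed(11)
  gam <- make_gamete(g)
  for (l in 1:3) {
    se <- sqrt(p[l] * (1 - p[l]) / 2e4)
    expect_lt(abs(mean(gam[, l]) - mean(g[, l]) / 2), 4 * se)
  }
})
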