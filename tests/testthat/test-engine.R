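test_that("scenario presets fix the documented switches", {
  expect_equal(scenario_config("A")$h2, 0)
  expect_equal(scenario_config("B")$h2, 1)
  expect_equal(scenario_config("C")$mortality_mode, "none")
  expect_false(scenario_config("D")$differential_reproduction)
  expect_equal(scenario_config("E")$mortality_mode, "typeI_only")
  expect_equal(scenario_config("F")$mortality_mode, "typeII_only")
  expect_equal(scenario_config("G")$h2, 0.6)
  expect_equal(scenario_config("Ha")$phenology$frost_k, 0.1)
  expect_equal(scenario_config("Hb")$frost_k, 0.2)
  expect_error(scenario_config("Z"), "unknown scenario")
  expect_error(scenario_config("B", adult_years = 7), "multiple")
  # explicit overrides beat the preset
  expect_equal(scenario_config("B", h2 = 0.3)$h2, 0.3)
})

test_that("founders are initialized in five equal elevational bands at age 40", {
  cfg <- scenario_config("B")
  eff <- draw_allelic_effects(seed = 1)
  st <- initialize_population(cfg, eff, seed = 2)
  expect_equal(nrow(st$trees), 500)
  expect_true(all(st$trees$age == 40L))
  bands <- table(cut(st$trees$elevation,
                     c(780, 820, 980, 1020, 1180, 1220, 1380, 1420, 1580,
                       1620)))
  expect_equal(as.integer(bands[c(1, 3, 5, 7, 9)]), rep(100L, 5))
  expect_true(all(st$trees$x >= 0 & st$trees$x <= 200))
  # reproducible founders
  st2 <- initialize_population(cfg, eff, seed = 2)
  expect_identical(st$trees, st2$trees)
})

test_that("neutral pre-evolution builds differentiation without selection", {
  cfg <- scenario_config("B", n_founders = 150, preevo_fecundity = 4)
  eff <- draw_allelic_effects(seed = 3)
  st <- initialize_population(cfg, eff, seed = 4)
  freq_by_band <- function(trees) {
    g <- do.call(rbind, trees$genotype)
    band <- bin_populations(trees$elevation)
    sapply(split(seq_len(nrow(trees)), band), function(i) {
      colMeans(g[i, , drop = FALSE]) / 2
    })
  }
  v0 <- mean(apply(freq_by_band(st$trees), 1, stats::var))
  out <- neutral_preevolution(st, n_gen = 3, seed = 5)
  expect_false(out$collapsed)
  expect_lte(nrow(out$trees), cfg$n_founders)
  expect_gt(nrow(out$trees), 0)
  # among-band allele-frequency variance grows from its founder level
  v3 <- mean(apply(freq_by_band(out$trees), 1, stats::var))
  expect_gt(v3, v0)
})

test_that("heritability does not affect genotype dynamics without selection", {
  effA <- draw_allelic_effects(seed = 6)
  cfgA <- scenario_config("A", n_founders = 100)
  cfgB <- scenario_config("B", n_founders = 100)
  gA <- neutral_preevolution(initialize_population(cfgA, effA, seed = 7),
                             n_gen = 2, seed = 8)
  gB <- neutral_preevolution(initialize_population(cfgB, effA, seed = 7),
                             n_gen = 2, seed = 8)
  expect_identical(genotype_matrix(gA$trees), genotype_matrix(gB$trees))
})

test_that("a generation reproduces only in the late adult years", {
  cfg <- desk_config("B")
  sim <- run_scenario(cfg, seed = 11)
  by <- sim$reps[[1]]$generations[[1]]$band_years
  early <- dplyr::filter(by, year < cfg$repro_start)
  late <- dplyr::filter(by, year >= cfg$repro_start)
  expect_true(all(early$seeds == 0))
  expect_gt(sum(late$seeds), 0)
})

test_that("no tree dies in the no-mortality scenario", {
  sim <- run_scenario(desk_config("C"), seed = 12)
  deaths <- dplyr::bind_rows(purrr::map(sim$reps[[1]]$generations, "deaths"))
  expect_equal(nrow(deaths), 0)
})

test_that("generations never overlap and cohorts enter at age 40", {
  sim <- run_scenario(desk_config("B"), seed = 13)
  gens <- sim$reps[[1]]$generations
  expect_true(all(purrr::map_lgl(gens,
                                 function(g) all(g$cohort$age == 40L))))
  ids <- purrr::map(gens, function(g) g$cohort$id)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
})

test_that("a run with no possible recruitment collapses gracefully", {
  cfg <- desk_config("B", seedling_survival = 0)
  sim <- run_scenario(cfg, seed = 14)
  expect_true(sim$reps[[1]]$collapsed)
  expect_length(sim$reps[[1]]$generations, 1L)
})

test_that("identical master seeds give bit-identical scenario runs", {
  cfg <- desk_config("B", n_repetitions = 2)
  s1 <- run_scenario(cfg, seed = 15)
  s2 <- run_scenario(cfg, seed = 15)
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(s1$reps[[2]]$generations[[2]]$band_years,
                   s2$reps[[2]]$generations[[2]]$band_years)
  # repetitions differ in founders but share the allelic effects
  st1 <- initialize_population(cfg, s1$effects,
                               derive_seed(15, "founders1"))
  st2 <- initialize_population(cfg, s1$effects,
                               derive_seed(15, "founders2"))
  expect_false(identical(st1$trees$x, st2$trees$x))
})

test_that("tidiers and plots summarise a simulation", {
  sim <- run_scenario(desk_config("B"), seed = 16)
  td <- tidy(sim)
  expect_true(all(c("repetition", "generation", "band", "n_trees",
                    "f_crit_mean") %in% names(td)))
  gl <- glance(sim)
  expect_equal(gl$scenario, "B")
  expect_equal(gl$n_repetitions, 1L)
  for (type in c("cb", "trait", "population")) {
    expect_s3_class(autoplot(sim, type = type), "ggplot")
  }
})
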