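# Demography: allometric growth, carbon-starvation mortality, reserve-driven
# seed production, spatial mating with selfing and size-dependent male
# fertility, seed rain onto the cell grid, and density-dependent recruitment.

#' Allometry and recruitment-size parameters
#'
#' Simple configurable allometries: a cylindrical stem of fixed form factor
#' converts wood carbon to a diameter increment; height and crown projection
#' follow power laws of DBH (coefficients chosen so a 13.8-cm recruit stands
#' about 9 m tall with a crown of roughly 12 m2).
#'
#' @param wood_density Stem dry-wood density (g cm-3).
#' @param carbon_frac Carbon fraction of dry mass.
#' @param form_factor Stem form factor (cylinder fraction).
#' @param h_coef,h_exp Height (m) = `h_coef * DBH^h_exp` (DBH in cm).
#' @param cp_coef,cp_exp Crown projection (m2) = `cp_coef * DBH^cp_exp`.
#' @param mu_h,sd_h Mean and SD of recruit height (m; 9 and 0.34).
#' @param mu_dbh,sd_dbh Mean and SD of recruit DBH (cm; 13.8 and 0.9).
#' @param recruit_pos_sd SD (m) of the Gaussian placement of a recruit around
#'   its mother when the mother sits in the same cell.
#' @return A list of allometry settings.
#' @export
allometry_params <- function(wood_density = 0.55, carbon_frac = 0.5,
                             form_factor = 0.5,
                             h_coef = 1.43, h_exp = 0.7,
                             cp_coef = 0.5, cp_exp = 1.2,
                             mu_h = 9, sd_h = 0.34,
                             mu_dbh = 13.8, sd_dbh = 0.9,
                             recruit_pos_sd = 5) {
  as.list(environment())
}

#' Stem carbon, height and crown projection from DBH
#'
#' @param dbh Diameter at breast height (cm).
#' @param height Tree height (m).
#' @param allom [allometry_params()].
#' @return `stem_carbon()`: stem carbon (gC); `height_from_dbh()`: height (m);
#'   `crown_area_from_dbh()`: crown projection (m2).
#' @export
stem_carbon <- function(dbh, height, allom = allometry_params()) {
  vol_cm3 <- allom$form_factor * (pi / 4) * dbh^2 * (height * 100)
  vol_cm3 * allom$wood_density * allom$carbon_frac
}

#' @rdname stem_carbon
#' @export
height_from_dbh <- function(dbh, allom = allometry_params()) {
  allom$h_coef * dbh^allom$h_exp
}

#' @rdname stem_carbon
#' @export
crown_area_from_dbh <- function(dbh, allom = allometry_params()) {
  allom$cp_coef * dbh^allom$cp_exp
}

#' Convert a year's wood allocation into a DBH increment
#'
#' The wood carbon allocated per unit crown area is scaled to the whole tree,
#' converted to stem volume, and the cylindrical allometry is inverted at the
#' current height; height and crown projection are then updated from the new
#' DBH. A zero allocation leaves the tree unchanged, and the inversion is
#' concave: doubling the wood carbon less than doubles the increment.
#'
#' @param dbh,height,crown_area Current dimensions (cm, m, m2).
#' @param wood_alloc Wood allocation (gC m-2 crown).
#' @param allom [allometry_params()].
#' @return A list with updated `dbh`, `height` and `crown_area` vectors.
#' @export
dbh_growth <- function(dbh, height, crown_area, wood_alloc,
                       allom = allometry_params()) {
  wood_c <- pmax(wood_alloc, 0) * crown_area
  dvol <- wood_c / (allom$wood_density * allom$carbon_frac)
  dbh_new <- sqrt(dbh^2 + dvol / (allom$form_factor * (pi / 4) * height * 100))
  list(
    dbh = dbh_new,
    height = height_from_dbh(dbh_new, allom),
    crown_area = crown_area_from_dbh(dbh_new, allom)
  )
}

#' Carbon-starvation mortality rules
#'
#' A tree dies of Type I mortality when its end-of-year carbon reserves fall
#' below the critical level (45 gC m-2) and of Type II mortality when the
#' pre-budburst reserve deficit exceeds its maximum tolerable value
#' (160 gC m-2). `mode` masks either or both rules (for the no-mortality and
#' single-mortality scenarios). Type I is checked first, so each dead tree has
#' exactly one recorded cause.
#'
#' @param summary Annual summary tibble from [simulate_physio_year()] (columns
#'   `cum_cr`, `bb_deficit`).
#' @param thresholds List with `cum_cr_crit` (gC m-2) and `bb_crit` (gC m-2).
#' @param mode One of `"both"`, `"none"`, `"typeI_only"`, `"typeII_only"`.
#' @return A tibble with logical `alive` and character `cause` (`"none"`,
#'   `"typeI"`, `"typeII"`).
#' @export
#' @examples
#' mortality_check(tibble::tibble(cum_cr = 44, bb_deficit = 0))
mortality_check <- function(summary,
                            thresholds = list(cum_cr_crit = 45, bb_crit = 160),
                            mode = c("both", "none", "typeI_only",
                                     "typeII_only")) {
  mode <- match.arg(mode)
  type1 <- summary$cum_cr < thresholds$cum_cr_crit
  type2 <- summary$bb_deficit > thresholds$bb_crit
  if (mode %in% c("none", "typeII_only")) type1 <- rep(FALSE, nrow(summary))
  if (mode %in% c("none", "typeI_only")) type2 <- rep(FALSE, nrow(summary))
  cause <- dplyr::case_when(type1 ~ "typeI", type2 ~ "typeII", TRUE ~ "none")
  tibble::tibble(alive = cause == "none", cause = cause)
}

#' Primary seed production from accumulated reserves
#'
#' A tree reproduces only if its end-of-year reserves exceed the critical
#' level for seed production; it then converts a fixed fraction of its
#' reserves (scaled by crown projection) into seeds at a fixed carbon cost per
#' seed, and that carbon is debited from the reserve pool.
#'
#' @param b_res End-of-year reserves (gC m-2).
#' @param crown_area Crown projection (m2).
#' @param s_b_res Critical reserve level for reproduction (gC m-2, 100).
#' @param r_sp Rate of seed production (0.05).
#' @param seed_cost Carbon cost of one seed (gC, 0.45).
#' @return A list with integer `n_seeds` and `b_res` after the debit.
#' @export
#' @examples
#' primary_seed_production(200, crown_area = 10)$n_seeds  # 222
primary_seed_production <- function(b_res, crown_area, s_b_res = 100,
                                    r_sp = 0.05, seed_cost = 0.45) {
  stopifnot(s_b_res > 0, r_sp > 0, seed_cost > 0)
  produce <- b_res > s_b_res
  n_seeds <- ifelse(produce,
                    floor(r_sp * b_res * crown_area / seed_cost), 0)
  debit <- ifelse(produce, r_sp * b_res, 0)
  list(n_seeds = as.integer(n_seeds), b_res = b_res - debit)
}

#' Effective fecundity at germination
#'
#' Discounts the primary seed crop by the rates of empty seeds, seed survival
#' and germination, yielding the expected number of germination-stage recruits
#' contributed by the tree.
#'
#' @param n_seeds Primary seed count.
#' @param r_es Rate of empty seeds (0.33).
#' @param r_ss Rate of seed survival (0.15).
#' @param r_sg Rate of seed germination (0.485).
#' @return Real-valued effective fecundity.
#' @export
effective_fecundity <- function(n_seeds, r_es = 0.33, r_ss = 0.15,
                                r_sg = 0.485) {
  rates <- c(r_es, r_ss, r_sg)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("seed-fate rates must lie in [0, 1].")
  }
  n_seeds * (1 - r_es) * r_ss * r_sg
}

#' Exponential-power dispersal kernel
#'
#' Two-dimensional kernel `p(r) = b / (2 pi a^2 Gamma(2/b)) exp(-(r/a)^b)`
#' parameterised by its mean dispersal distance `delta = a Gamma(3/b) /
#' Gamma(2/b)` and shape `b`; `b = 1` recovers the pure exponential kernel
#' with `delta = 2a`. Defaults for pollen (mean 37.9 m, shape 0.97) and seed
#' (mean 18.13 m, shape 0.31) kernels are provided.
#'
#' @param mean_distance Mean dispersal distance delta (m).
#' @param shape Shape parameter b.
#' @return A list with `mean_distance`, `shape` and derived `scale` a (m),
#'   with class `phenoevo_kernel`.
#' @export
#' @examples
#' dispersal_kernel(10, shape = 1)$scale  # 5: delta = 2a for b = 1
dispersal_kernel <- function(mean_distance, shape) {
  stopifnot(mean_distance > 0, shape > 0)
  scale <- mean_distance * gamma(2 / shape) / gamma(3 / shape)
  structure(
    list(mean_distance = mean_distance, shape = shape, scale = scale),
    class = "phenoevo_kernel"
  )
}

#' @rdname dispersal_kernel
#' @export
pollen_kernel <- function(mean_distance = 37.9, shape = 0.97) {
  dispersal_kernel(mean_distance, shape)
}

#' @rdname dispersal_kernel
#' @export
seed_kernel <- function(mean_distance = 18.13, shape = 0.31) {
  dispersal_kernel(mean_distance, shape)
}

#' Kernel density at distance r
#'
#' Probability density per unit area that a propagule emitted at the origin
#' lands at distance `r`.
#'
#' @param r Distance (m), non-negative.
#' @param kernel A [dispersal_kernel()].
#' @return Density (m-2).
#' @export
kernel_density <- function(r, kernel) {
  if (any(r < 0)) rlang::abort("`r` must be non-negative.")
  b <- kernel$shape
  a <- kernel$scale
  b / (2 * pi * a^2 * gamma(2 / b)) * exp(-(r / a)^b)
}

#' Sample dispersal distances from a kernel
#'
#' The radial distance satisfies `(r/a)^b ~ Gamma(2/b, 1)`, which gives an
#' exact sampler for the exponential-power family. Uses the current RNG state.
#'
#' @param n Number of distances.
#' @param kernel A [dispersal_kernel()].
#' @return Numeric vector of distances (m).
#' @export
sample_kernel_distance <- function(n, kernel) {
  b <- kernel$shape
  kernel$scale * stats::rgamma(n, shape = 2 / b)^(1 / b)
}

# First-order mirror images of positions across the four domain edges,
# implementing reflecting borders for dispersal distance computations.
reflected_positions <- function(x, y, dom = domain_geometry()) {
  list(
    x = cbind(x, -x, 2 * dom$xmax - x, x, x),
    y = cbind(y, y, y, -y, 2 * dom$ymax - y)
  )
}

# Kernel density between source points (sx, sy) and target points (tx, ty)
# under reflecting borders: densities of the direct path and of the four
# first-order mirror images of the source are summed. Returns a matrix
# (targets x sources).
reflected_kernel <- function(sx, sy, tx, ty, kernel, dom = domain_geometry()) {
  imgs <- reflected_positions(sx, sy, dom)
  out <- matrix(0, length(tx), length(sx))
  for (k in 1:5) {
    d <- sqrt(outer(tx, imgs$x[, k], `-`)^2 + outer(ty, imgs$y[, k], `-`)^2)
    out <- out + kernel_density(d, kernel)
  }
  out
}

#' Pollen contributions of candidate fathers to one seed tree
#'
#' The outcrossing contribution of candidate k to mother j is proportional to
#' the pollen-kernel density of the j-k distance (computed under reflecting
#' borders, summing the four first-order mirror images) times the candidate's
#' male fertility `DBH^gamma_m`. The mother is excluded and the weights
#' normalised.
#'
#' @param mother One-row tibble (or list) with `x`, `y`, `id`.
#' @param candidates Tibble of candidate fathers with `id`, `x`, `y`, `dbh`.
#' @param kernel Pollen [dispersal_kernel()].
#' @param gamma_m Male-fertility exponent on DBH (0.82).
#' @return A tibble with `id` and normalised probability `prob` over
#'   candidates other than the mother.
#' @export
pollen_contributions <- function(mother, candidates, kernel = pollen_kernel(),
                                 gamma_m = 0.82) {
  others <- candidates[candidates$id != mother$id, , drop = FALSE]
  if (nrow(others) == 0L) {
    rlang::abort("no outcross candidates available.")
  }
  dens <- reflected_kernel(others$x, others$y, mother$x, mother$y, kernel)
  w <- as.numeric(dens) * others$dbh^gamma_m
  tibble::tibble(id = others$id, prob = w / sum(w))
}

#' Draw fathers for a mother's seeds
#'
#' Each seed is selfed with probability `selfing`; otherwise its father is
#' drawn from the outcross pollen-contribution probabilities. Uses the current
#' RNG state.
#'
#' @param mother,candidates,kernel,gamma_m As in [pollen_contributions()].
#' @param n Number of seeds.
#' @param selfing Selfing rate (0.025).
#' @return Integer vector of father ids.
#' @export
sample_father <- function(mother, candidates, n, kernel = pollen_kernel(),
                          gamma_m = 0.82, selfing = 0.025) {
  contrib <- pollen_contributions(mother, candidates, kernel, gamma_m)
  selfed <- stats::runif(n) < selfing
  out <- rep(mother$id, n)
  n_out <- sum(!selfed)
  if (n_out > 0) {
    out[!selfed] <- sample(contrib$id, n_out, replace = TRUE,
                           prob = contrib$prob)
  }
  out
}

#' The recruitment grid
#'
#' The 200 x 1000 m domain divided into 500 cells of 20 x 20 m.
#'
#' @return A tibble with `cell` (id), `cx`, `cy` (cell centres, m) and
#'   `area` (m2).
#' @export
make_grid <- function() {
  dom <- domain_geometry()
  nx <- dom$xmax %/% dom$cell_size
  ny <- dom$ymax %/% dom$cell_size
  g <- tidyr::expand_grid(iy = seq_len(ny), ix = seq_len(nx))
  tibble::tibble(
    cell = seq_len(nrow(g)),
    cx = (g$ix - 0.5) * dom$cell_size,
    cy = (g$iy - 0.5) * dom$cell_size,
    area = dom$cell_size^2
  )
}

#' Seed-rain intensity of mothers on grid cells
#'
#' The intensity of seed rain of mother j at the centre of cell i is her
#' effective fecundity times the seed-kernel density of the i-j distance
#' (reflecting borders).
#'
#' @param mothers Tibble with `x`, `y` and effective fecundity `fecundity`.
#' @param grid Tibble from [make_grid()].
#' @param kernel Seed [dispersal_kernel()].
#' @return A matrix of intensities (cells x mothers), per m2.
#' @export
seed_rain <- function(mothers, grid, kernel = seed_kernel()) {
  stopifnot(all(mothers$fecundity >= 0))
  dens <- reflected_kernel(mothers$x, mothers$y, grid$cx, grid$cy, kernel)
  sweep(dens, 2, mothers$fecundity, `*`)
}

#' Place recruits within a cell
#'
#' Positions are uniform within the 20 x 20 m cell unless the mother sits in
#' the same cell, in which case they are drawn from an isotropic Gaussian
#' around her position, truncated to the domain. Uses the current RNG state.
#'
#' @param n Number of recruits.
#' @param cell One-row tibble from [make_grid()].
#' @param mother One-row tibble with `x`, `y` (or `NULL` for uniform
#'   placement).
#' @param pos_sd Gaussian placement SD (m).
#' @return A tibble with `x`, `y`.
#' @export
place_recruit <- function(n, cell, mother = NULL, pos_sd = 5) {
  dom <- domain_geometry()
  half <- dom$cell_size / 2
  in_cell <- !is.null(mother) &&
    abs(mother$x - cell$cx) <= half && abs(mother$y - cell$cy) <= half
  if (in_cell) {
    tibble::tibble(
      x = clamp(stats::rnorm(n, mother$x, pos_sd), 0, dom$xmax),
      y = clamp(stats::rnorm(n, mother$y, pos_sd), 0, dom$ymax)
    )
  } else {
    tibble::tibble(
      x = stats::runif(n, cell$cx - half, cell$cx + half),
      y = stats::runif(n, cell$cy - half, cell$cy + half)
    )
  }
}

# Area of the intersection of two discs with radii r1, r2 at distance d.
disc_intersection <- function(d, r1, r2) {
  lo <- pmin(r1, r2)
  hi <- pmax(r1, r2)
  out <- numeric(length(d))
  inside <- d <= hi - lo
  out[inside] <- pi * lo[inside]^2
  lens <- d < r1 + r2 & !inside
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    out[lens] <- a^2 * acos(clamp((dd^2 + a^2 - b^2) / (2 * dd * a), -1, 1)) +
      b^2 * acos(clamp((dd^2 + b^2 - a^2) / (2 * dd * b), -1, 1)) -
      0.5 * sqrt(pmax(
        (-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b), 0
      ))
  }
  out
}

#' Density-dependent crown-overlap thinning
#'
#' Crowns are discs of the trees' crown projection centred on their positions.
#' No surviving pair may share more than `max_overlap` (30%) of the smaller
#' crown's area: violating pairs are visited in random order and one member of
#' each, chosen at random, is removed (removals never create new violations,
#' so the survivors satisfy the constraint exactly). The process is
#' independent of the trees' genotypes and phenology. Uses the current RNG
#' state.
#'
#' @param trees Tibble with `x`, `y`, `crown_area`.
#' @param max_overlap Maximum tolerated overlap fraction of the smaller crown.
#' @return The surviving rows of `trees`.
#' @export
crown_overlap_thinning <- function(trees, max_overlap = 0.30) {
  n <- nrow(trees)
  if (n < 2L) return(trees)
  r <- sqrt(trees$crown_area / pi)
  pairs <- neighbour_pairs(trees$x, trees$y, max_dist = 2 * max(r))
  if (nrow(pairs) == 0L) return(trees)
  d <- sqrt((trees$x[pairs$i] - trees$x[pairs$j])^2 +
              (trees$y[pairs$i] - trees$y[pairs$j])^2)
  touching <- d < r[pairs$i] + r[pairs$j]
  pairs <- pairs[touching, , drop = FALSE]
  d <- d[touching]
  if (nrow(pairs) == 0L) return(trees)
  ovl <- disc_intersection(d, r[pairs$i], r[pairs$j]) /
    (pi * pmin(r[pairs$i], r[pairs$j])^2)
  viol <- pairs[ovl > max_overlap, , drop = FALSE]
  if (nrow(viol) == 0L) return(trees)
  alive <- rep(TRUE, n)
  for (k in sample.int(nrow(viol))) {
    i <- viol$i[k]; j <- viol$j[k]
    if (alive[i] && alive[j]) {
      alive[if (stats::runif(1) < 0.5) i else j] <- FALSE
    }
  }
  trees[alive, , drop = FALSE]
}

# Candidate neighbour pairs (i < j) within max_dist, via spatial bucketing:
# only trees in the same or adjacent buckets can be close enough to overlap.
neighbour_pairs <- function(x, y, max_dist) {
  n <- length(x)
  pts <- tibble::tibble(
    idx = seq_len(n),
    bx = floor(x / max_dist),
    by = floor(y / max_dist)
  )
  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  pieces <- purrr::map(seq_len(nrow(offsets)), function(o) {
    shifted <- dplyr::mutate(
      pts,
      bx = .data$bx + offsets$dx[o],
      by = .data$by + offsets$dy[o]
    )
    m <- dplyr::inner_join(
      pts, shifted,
      by = c("bx", "by"), suffix = c("_i", "_j"),
      relationship = "many-to-many"
    )
    dplyr::filter(m, .data$idx_i < .data$idx_j)
  })
  out <- dplyr::distinct(
    dplyr::bind_rows(pieces),
    i = .data$idx_i, j = .data$idx_j
  )
  out
}
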