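# Quantitative genetics of the budburst forcing requirement F_critBB:
# ten independent biallelic loci with purely additive effects.

#' Draw the per-locus allelic effects of the forcing requirement
#'
#' The trait mean `mu` is split equally across loci: every locus has midpoint
#' `m_l = mu / n_loci`, and genotypes A1A1, A1A2, A2A2 at locus l contribute
#' `m_l + alpha_l`, `m_l`, `m_l - alpha_l`. Allelic effects are drawn from a
#' Gaussian of mean `mu / (2 n_loci)` and standard deviation `mu / (8 n_loci)`
#' (an L-shaped QTL-effect distribution), redrawn until they fall inside
#' `[0, mu / n_loci]` so that all genotypic values lie in `[0, 2 mu]`. Effects
#' are constant for a whole simulation: all replicate runs of a scenario share
#' one draw.
#'
#' @param n_loci Number of loci (default 10).
#' @param mu Population mean of the forcing requirement (degC, default 190).
#' @param seed Integer seed for the effects stream.
#' @return A tibble with columns `locus`, `m` (midpoint, degC) and `alpha`
#'   (allelic effect, degC).
#' @export
#' @examples
#' draw_allelic_effects(seed = 1)
draw_allelic_effects <- function(n_loci = 10, mu = 190, seed = 1) {
  if (!is.numeric(mu) || mu <= 0) rlang::abort("`mu` must be positive.")
  stopifnot(n_loci >= 1)
  n_loci <- as.integer(n_loci)
  m_l <- mu / n_loci
  with_stream(seed, {
    alpha <- numeric(n_loci)
    for (l in seq_len(n_loci)) {
      repeat {
        a <- stats::rnorm(1, mean = mu / (2 * n_loci), sd = mu / (8 * n_loci))
        if (a >= 0 && a <= m_l) break
      }
      alpha[l] <- a
    }
    tibble::tibble(locus = seq_len(n_loci), m = m_l, alpha = alpha)
  })
}

#' Founder genotypes under Hardy-Weinberg equilibrium
#'
#' Per-locus frequencies of allele A1 are drawn from Uniform(0, 1) (unless
#' supplied), and each individual's genotype at locus l is drawn with
#' Hardy-Weinberg probabilities p^2, 2pq, q^2 for A1A1, A1A2, A2A2. Genotypes
#' are coded as the per-locus count of A1 alleles (0, 1 or 2).
#'
#' @param n_individuals Number of founders.
#' @param n_loci Number of loci.
#' @param seed Integer seed for the founder stream; ignored if `NULL` (the
#'   current RNG state is used).
#' @param freqs Optional numeric vector of per-locus A1 frequencies to use
#'   instead of uniform draws.
#' @return A list with `genotypes` (integer matrix, individuals x loci) and
#'   `freqs` (the per-locus A1 frequencies used).
#' @export
init_founder_genotypes <- function(n_individuals, n_loci = 10, seed = NULL,
                                   freqs = NULL) {
  stopifnot(n_individuals >= 1, n_loci >= 1)
  n_individuals <- as.integer(n_individuals)
  n_loci <- as.integer(n_loci)
  with_stream(seed, {
    if (is.null(freqs)) {
      freqs <- stats::runif(n_loci)
    } else {
      stopifnot(length(freqs) == n_loci, all(freqs >= 0 & freqs <= 1))
    }
    g <- vapply(seq_len(n_loci), function(l) {
      stats::rbinom(n_individuals, size = 2, prob = freqs[l])
    }, integer(n_individuals))
    g <- matrix(as.integer(g), nrow = n_individuals, ncol = n_loci)
    list(genotypes = g, freqs = freqs)
  })
}

#' Genotypic value of the forcing requirement
#'
#' The additive value is `sum_l m_l + alpha_l * (state_l - 1)` where `state_l`
#' counts A1 alleles; an all-heterozygote genotype scores exactly the trait
#' mean `sum_l m_l`.
#'
#' @param genotypes Integer matrix (individuals x loci) or a single genotype
#'   vector.
#' @param effects Tibble from [draw_allelic_effects()].
#' @return Numeric vector of genotypic values (degC).
#' @export
genotypic_value <- function(genotypes, effects) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  if (ncol(genotypes) != nrow(effects)) {
    rlang::abort("genotype length does not match the number of loci.")
  }
  as.numeric(sum(effects$m) + (genotypes - 1) %*% effects$alpha)
}

#' Trait model: heritability handling for the forcing requirement
#'
#' Three regimes: fully heritable (`h2 = 1`, phenotype equals genotypic
#' value), non-heritable control (`h2 = 0`, phenotypes drawn from
#' Normal(mu, V_P) regardless of genotype) and partial heritability
#' (`0 < h2 < 1`, phenotype = genotypic value + Normal(0, V_E) with
#' `V_E = V_A (1 - h2) / h2` and `V_A` the configured additive variance).
#'
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param V_P Phenotypic variance used by the control regime ((degC)^2,
#'   default 22).
#' @param V_A Additive variance used to size `V_E` under partial heritability
#'   ((degC)^2, default 22).
#' @param mu Trait mean (degC).
#' @return A list with class `phenoevo_trait_model`.
#' @export
trait_model <- function(h2 = 1, V_P = 22, V_A = 22, mu = 190) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 < 0 || h2 > 1) {
    rlang::abort("`h2` must be a single value in [0, 1].")
  }
  mode <- if (h2 == 0) "control" else if (h2 == 1) "heritable" else "partial"
  V_E <- switch(mode,
    control = V_P,
    heritable = 0,
    partial = V_A * (1 - h2) / h2
  )
  structure(
    list(h2 = h2, V_P = V_P, V_A = V_A, V_E = V_E, mu = mu, mode = mode),
    class = "phenoevo_trait_model"
  )
}

#' Assign lifetime phenotypic values of the forcing requirement
#'
#' A tree's phenotype is fixed at creation and constant for its lifetime.
#' Under full heritability the genotypic value is returned unchanged; under
#' the control regime phenotypes are Gaussian draws around the trait mean;
#' under partial heritability a Gaussian environmental deviation is added.
#' Uses the current RNG state (wrap in a seeded stream for reproducibility);
#' all modes consume exactly one deviate per tree, so runs that differ only
#' in heritability share the same randomness everywhere else (common random
#' numbers across scenarios).
#'
#' @param genetic_value Numeric vector of genotypic values (degC).
#' @param model A [trait_model()].
#' @return Numeric vector of phenotypic forcing requirements (degC).
#' @export
phenotype_fcrit <- function(genetic_value, model = trait_model()) {
  n <- length(genetic_value)
  dev <- stats::rnorm(n)
  switch(model$mode,
    heritable = genetic_value,
    control = model$mu + sqrt(model$V_P) * dev,
    partial = genetic_value + sqrt(model$V_E) * dev
  )
}

#' Form gametes by independent segregation
#'
#' Loci are unlinked: each gamete carries, per locus, one of the parent's two
#' alleles with equal probability, independently across loci. There is no
#' mutation. Returns the per-locus count of A1 alleles carried by each gamete
#' (0 or 1). Uses the current RNG state.
#'
#' @param genotypes Integer matrix (parents x loci) or a single genotype
#'   vector; one gamete is produced per row.
#' @return Integer matrix (parents x loci) of transmitted A1 counts.
#' @export
make_gamete <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  n <- nrow(genotypes)
  l <- ncol(genotypes)
  # homozygotes transmit deterministically; heterozygotes flip a fair coin
  u <- matrix(stats::runif(n * l), n, l)
  out <- matrix(0L, n, l)
  out[genotypes == 2L] <- 1L
  het <- genotypes == 1L
  out[het] <- as.integer(u[het] < 0.5)
  out
}

#' Additive genetic variance from allele frequencies
#'
#' For purely additive biallelic loci the within-population additive variance
#' is `sum_l 2 p_l (1 - p_l) alpha_l^2`.
#'
#' @param freqs Per-locus A1 frequencies.
#' @param effects Tibble from [draw_allelic_effects()].
#' @return Additive variance ((degC)^2).
#' @export
additive_variance <- function(freqs, effects) {
  if (any(freqs < 0 | freqs > 1)) {
    rlang::abort("allele frequencies must lie in [0, 1].")
  }
  stopifnot(length(freqs) == nrow(effects))
  sum(2 * freqs * (1 - freqs) * effects$alpha^2)
}

#' Per-locus allele frequencies of a genotype matrix
#'
#' @param genotypes Integer matrix (individuals x loci) of A1 counts.
#' @return Numeric vector of A1 frequencies.
#' @export
allele_frequencies <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  colMeans(genotypes) / 2
}
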