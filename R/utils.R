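# Internal helpers: seeded RNG streams, small numeric utilities.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Each stochastic component (founders, allelic effects, climate, mating,
#' dispersal, thinning, ...) draws from its own named stream so that components
#' are reproducible in isolation: the sub-seed depends only on the master seed
#' and the stream label, never on how much randomness other components consumed.
#'
#' @param master Integer master seed.
#' @param stream Character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "founders1")
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(stream)) {
    # 31-bit multiplicative mixing; stays exactly representable in doubles
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary, seeded RNG state
#'
#' Restores the caller's `.Random.seed` afterwards, so library internals never
#' perturb user-level randomness.
#'
#' @param seed Integer seed (may be `NULL` to leave the RNG alone).
#' @param code Expression to evaluate.
#' @keywords internal
with_stream <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulation domain geometry
#'
#' The stand is a 20-ha rectangle of 200 m (x) by 1000 m (y). The y axis maps
#' linearly onto elevation: a tree at y metres sits at `700 + y` m a.s.l., so
#' the domain spans the 700-1700 m gradient.
#'
#' @return A list with fields `xmax`, `ymax`, `elev_min`, `elev_max`,
#'   `cell_size` (m) and `n_cells`.
#' @export
#' @examples
#' domain_geometry()$n_cells  # 500 cells of 20 x 20 m
domain_geometry <- function() {
  list(
    xmax = 200, ymax = 1000,
    elev_min = 700, elev_max = 1700,
    cell_size = 20,
    n_cells = (200 %/% 20) * (1000 %/% 20)
  )
}

elevation_of <- function(y) 700 + y
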