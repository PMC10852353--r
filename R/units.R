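#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' The package-wide value used in every thermal quantity.
#' @export
boltzmann_kcal <- 0.0019872

#' Thermal energy k_B * T
#'
#' @param temperature temperature in Kelvin (> 0).
#' @return k_B T in kcal/mol.
#' @export
#' @examples
#' kBT(310) # 0.616032
kBT <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("temperature must be positive")
  }
  boltzmann_kcal * temperature
}

# Internal time unit sqrt(amu A^2 mol / kcal) expressed in fs. Timesteps given
# in fs and frictions in ps^-1 are converted through this factor so that
# force/mass has units of A per internal-time^2.
akma_fs <- 48.88821

#' Derive a reproducible sub-stream seed
#'
#' Counter-based derivation of per-operation seeds from a master seed and an
#' index (node, window, replica, stage ...), so that independently seeded
#' operations are reproducible regardless of call order.
#'
#' @param seed master integer seed.
#' @param index nonnegative integer counter.
#' @return an integer seed in 1 .. 2^31 - 20.
#' @export
derive_seed <- function(seed, index = 0L) {
  s <- as.numeric(seed) %% 2147483647
  x <- (s * 48271 + as.numeric(index) * 69621 + 12345) %% 2147483629
  as.integer(x + 1)
}

# Evaluate code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Trapezoidal rule on (x, y) with x strictly increasing.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
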