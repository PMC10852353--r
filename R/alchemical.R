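#' Paired alchemical end states with a known free-energy difference
#'
#' Builds toy alchemical transformations with closed-form Delta G, used to
#' validate thermodynamic-integration estimators and to calibrate the two-leg
#' thermodynamic cycles (pKa shift, ligand release). Mixing is linear:
#' V_lambda = (1 - lambda) V_A + lambda V_B, so dU/dlambda = V_B - V_A.
#'
#' Kinds:
#' \describe{
#'   \item{`harmonic-stiffness`}{harmonic well whose stiffness changes from
#'     `k_a` to `k_b` (with an optional energy `offset` on state B);
#'     Delta G = sum_j (k_B T / 2) ln(k_b_j / k_a_j) + offset.}
#'   \item{`well-offset`}{identical harmonic wells displaced in energy by
#'     `offset`; Delta G = offset.}
#'   \item{`release-toy`}{two legs (an annihilation in a binding "site"
#'     environment and in "bulk") built from harmonic-stiffness pairs with the
#'     same stiffness ratio, calibrated so that
#'     Delta G_site - Delta G_bulk = `dG_target` exactly.}
#' }
#'
#' @param kind one of `"harmonic-stiffness"`, `"well-offset"`, `"release-toy"`.
#' @param k_a,k_b end-state stiffnesses (kcal/mol/A^2, > 0).
#' @param offset energy offset of state B (kcal/mol).
#' @param dG_target requested site-minus-bulk Delta G for `release-toy`.
#' @param k_ratio stiffness ratio used inside the release-toy legs.
#' @param dimension coordinate dimension (default 1).
#' @param temperature temperature (K) entering the analytic Delta G.
#' @param masses per-coordinate masses (amu).
#' @return an `alchemical_pair` (fields `A`, `B`, `mixing(lambda)`, `dudl`,
#'   `analytic_dG`, `temperature`), or for `release-toy` a `release_toy` list
#'   with fields `site`, `bulk` (both `alchemical_pair`) and `analytic_dG`.
#' @export
#' @examples
#' p <- make_alchemical_pair("harmonic-stiffness", k_a = 1, k_b = exp(2))
#' p$analytic_dG # kBT(310)/2 * 2 = 0.616032
make_alchemical_pair <- function(kind = c("harmonic-stiffness", "well-offset",
                                          "release-toy"),
                                 k_a = 1, k_b = 2, offset = 0,
                                 dG_target = NULL, k_ratio = 2,
                                 dimension = 1, temperature = 310,
                                 masses = rep(1, dimension)) {
  kind <- match.arg(kind)
  if (kind == "release-toy") {
    if (is.null(dG_target)) stop("release-toy requires dG_target")
    site <- make_alchemical_pair("harmonic-stiffness", k_a = k_a,
                                 k_b = k_a * k_ratio, offset = dG_target,
                                 dimension = dimension,
                                 temperature = temperature, masses = masses)
    bulk <- make_alchemical_pair("harmonic-stiffness", k_a = k_a,
                                 k_b = k_a * k_ratio, offset = 0,
                                 dimension = dimension,
                                 temperature = temperature, masses = masses)
    site$label <- "release-site"; bulk$label <- "release-bulk"
    return(structure(list(site = site, bulk = bulk, analytic_dG = dG_target,
                          temperature = temperature),
                     class = "release_toy"))
  }
  if (any(k_a <= 0) || any(k_b <= 0)) stop("stiffnesses must be positive")
  ka <- rep(k_a, length.out = dimension)
  kb <- if (kind == "well-offset") ka else rep(k_b, length.out = dimension)
  A <- harmonic_potential(ka, dimension = dimension, masses = masses)
  B <- harmonic_potential(kb, dimension = dimension, masses = masses,
                          offset = offset)
  analytic <- if (kind == "well-offset") offset else {
    sum(kBT(temperature) / 2 * log(kb / ka)) + offset
  }
  mixing <- function(lambda) {
    stopifnot(lambda >= 0, lambda <= 1)
    potential(function(X) (1 - lambda) * A$energy(X) + lambda * B$energy(X),
              function(X) (1 - lambda) * A$gradient(X) + lambda * B$gradient(X),
              dimension, masses = masses,
              label = sprintf("mix(lambda=%g)", lambda), box = A$box)
  }
  structure(list(A = A, B = B, mixing = mixing,
                 dudl = function(X) B$energy(X) - A$energy(X),
                 analytic_dG = analytic, temperature = temperature,
                 dimension = dimension, masses = masses, label = kind),
            class = "alchemical_pair")
}

#' @export
print.alchemical_pair <- function(x, ...) {
  cat(sprintf("<alchemical_pair> %s, d=%d, analytic dG = %.6g kcal/mol at %g K\n",
              x$label, x$dimension, x$analytic_dG, x$temperature))
  invisible(x)
}

#' Boltzmann-quadrature Delta G of an alchemical pair
#'
#' Independent numerical oracle: -kT ln(Z_B / Z_A) by dense quadrature over the
#' end-state box (dimension <= 2).
#'
#' @param pair an `alchemical_pair`.
#' @param n_grid grid points per coordinate.
#' @return Delta G in kcal/mol.
#' @export
pair_quadrature_dg <- function(pair, n_grid = 2001) {
  d <- pair$dimension
  if (d > 2) stop("quadrature oracle limited to dimension <= 2")
  beta <- 1 / kBT(pair$temperature)
  box <- pair$A$box
  grids <- lapply(seq_len(d), function(j) seq(box[j, 1], box[j, 2],
                                              length.out = n_grid))
  X <- as.matrix(expand.grid(grids))
  ea <- pair$A$energy(X); eb <- pair$B$energy(X)
  ref <- min(ea, eb)
  za <- sum(exp(-beta * (ea - ref)))
  zb <- sum(exp(-beta * (eb - ref)))
  -kBT(pair$temperature) * log(zb / za)
}

#' Ornstein-Uhlenbeck CV time series
#'
#' Stationary Gaussian series with variance k_B T / stiffness and relaxation
#' rate stiffness / friction, generated with the exact AR(1) discretisation and
#' initialised from the stationary distribution. A fixture generator for the
#' trajectory-descriptor module.
#'
#' @param n number of frames (>= 2).
#' @param stiffness restoring stiffness (kcal/mol/A^2), scalar or one per CV.
#' @param temperature temperature (K).
#' @param friction friction (ps^-1 scale; sets the relaxation rate
#'   stiffness/friction per frame interval).
#' @param seed integer seed (required: series are reproducible by contract).
#' @param dt frame interval (ps).
#' @param labels optional coordinate labels.
#' @return a [cv_series()].
#' @export
make_ou_series <- function(n, stiffness = 1, temperature = 310, friction = 2,
                           seed, dt = 1, labels = NULL) {
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  if (any(stiffness <= 0)) stop("stiffness must be positive")
  if (any(friction <= 0)) stop("friction must be positive")
  if (missing(seed)) stop("seed must be given")
  d <- length(stiffness)
  v <- kBT(temperature) / stiffness        # stationary variance per coordinate
  phi <- exp(-stiffness / friction * dt)
  vals <- with_seed(seed, {
    out <- matrix(0, n, d)
    for (j in seq_len(d)) {
      x0 <- stats::rnorm(1, 0, sqrt(v[j]))
      eps <- stats::rnorm(n - 1, 0, sqrt(v[j] * (1 - phi[j]^2)))
      out[, j] <- c(x0, stats::filter(eps, phi[j], method = "recursive",
                                      init = x0))
    }
    out
  })
  cv_series(vals, dt = dt, labels = labels)
}
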