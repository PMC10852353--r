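#' Construct a CV-space potential
#'
#' A `potential` is a differentiable scalar energy field over a low-dimensional
#' CV vector. Both `energy` and `gradient` must be vectorised over
#' configurations: they receive an n x d matrix (one configuration per row) and
#' return, respectively, a length-n numeric vector and an n x d matrix.
#'
#' @param energy function(X) -> numeric(n); energies in kcal/mol.
#' @param gradient function(X) -> n x d matrix; kcal/mol/Angstrom.
#' @param dimension number of CVs (>= 1).
#' @param masses per-coordinate masses in amu (positive), used as the
#'   mass-weighted metric and as particle masses in Langevin sampling.
#' @param label free-text label.
#' @param box optional d x 2 matrix of per-coordinate sampling bounds. Used by
#'   quadrature oracles and finiteness checks.
#' @return an object of class `potential`.
#' @export
potential <- function(energy, gradient, dimension,
                      masses = rep(1, dimension), label = "potential",
                      box = NULL) {
  stopifnot(is.function(energy), is.function(gradient))
  dimension <- as.integer(dimension)
  if (dimension < 1) stop("dimension must be a positive integer")
  if (length(masses) == 1) masses <- rep(masses, dimension)
  if (length(masses) != dimension || any(masses <= 0)) {
    stop("masses must be positive and match the dimension")
  }
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 2)
    if (nrow(box) != dimension || any(box[, 2] <= box[, 1])) {
      stop("box must be a d x 2 matrix of increasing bounds")
    }
  }
  structure(list(dimension = dimension, energy = energy, gradient = gradient,
                 masses = masses, label = label, box = box),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat(sprintf("<potential> %s: %d CV(s), masses [%s] amu\n",
              x$label, x$dimension, paste(signif(x$masses, 4), collapse = ", ")))
  invisible(x)
}

# Coerce a vector or matrix to an n x d configuration matrix.
as_cv_matrix <- function(x, dimension) {
  if (is.null(dim(x))) {
    if (length(x) %% dimension != 0) {
      stop("configuration length is not a multiple of the dimension")
    }
    x <- matrix(x, ncol = dimension, byrow = TRUE)
  }
  if (ncol(x) != dimension) stop("configuration dimension mismatch")
  x
}

#' Check gradient consistency of a potential
#'
#' Compares the declared analytic gradient with a central finite difference at
#' the supplied points and returns the worst relative deviation.
#'
#' @param pot a [potential()].
#' @param points n x d matrix of evaluation points.
#' @param h finite-difference step.
#' @return maximum relative deviation (scalar).
#' @export
check_gradient <- function(pot, points, h = 1e-5) {
  X <- as_cv_matrix(points, pot$dimension)
  g <- pot$gradient(X)
  gn <- matrix(0, nrow(X), pot$dimension)
  for (j in seq_len(pot$dimension)) {
    Xp <- X; Xm <- X
    Xp[, j] <- Xp[, j] + h
    Xm[, j] <- Xm[, j] - h
    gn[, j] <- (pot$energy(Xp) - pot$energy(Xm)) / (2 * h)
  }
  scale <- pmax(sqrt(rowSums(g^2)), 1)
  max(abs(g - gn) / scale)
}

#' The Mueller-Brown surface
#'
#' The canonical three-well, two-saddle 2-D test surface for minimum-energy-path
#' algorithms, with its analytic gradient. Energies are in the surface's
#' canonical units.
#'
#' @return a [potential()] of dimension 2.
#' @export
#' @examples
#' mb <- muller_brown()
#' mb$energy(c(-0.558, 1.442)) # about -146.7 at the deepest minimum
muller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(X) {
    X <- as_cv_matrix(X, 2)
    v <- numeric(nrow(X))
    for (i in 1:4) {
      dx <- X[, 1] - x0[i]; dy <- X[, 2] - y0[i]
      v <- v + A[i] * exp(a[i] * dx^2 + b[i] * dx * dy + cc[i] * dy^2)
    }
    v
  }
  gradient <- function(X) {
    X <- as_cv_matrix(X, 2)
    gx <- numeric(nrow(X)); gy <- numeric(nrow(X))
    for (i in 1:4) {
      dx <- X[, 1] - x0[i]; dy <- X[, 2] - y0[i]
      e <- A[i] * exp(a[i] * dx^2 + b[i] * dx * dy + cc[i] * dy^2)
      gx <- gx + e * (2 * a[i] * dx + b[i] * dy)
      gy <- gy + e * (b[i] * dx + 2 * cc[i] * dy)
    }
    cbind(gx, gy, deparse.level = 0)
  }
  pot <- potential(energy, gradient, 2, label = "muller-brown",
                   box = rbind(c(-1.8, 1.2), c(-0.5, 2.2)))
  # Newton-refined stationary points of the surface
  attr(pot, "minima") <- rbind(c(-0.5582236346, 1.4417258418),
                               c(-0.0500108230, 0.4666941049),
                               c(0.6234994049, 0.0280377585))
  attr(pot, "saddles") <- rbind(c(-0.8220015587, 0.6243128028),
                                c(0.2124865820, 0.2929883251))
  pot
}

#' Harmonic well potential
#'
#' V(x) = sum_j k_j (x_j - c_j)^2 / 2.
#'
#' @param stiffness scalar or per-coordinate stiffness (kcal/mol/A^2, > 0).
#' @param center well center (defines the dimension unless given).
#' @param dimension optional dimension override.
#' @param masses per-coordinate masses in amu.
#' @param offset constant energy offset in kcal/mol.
#' @return a [potential()].
#' @export
harmonic_potential <- function(stiffness = 1, center = 0, dimension = length(center),
                               masses = rep(1, dimension), offset = 0) {
  if (any(stiffness <= 0)) stop("stiffness must be positive")
  k <- rep(stiffness, length.out = dimension)
  cen <- rep(center, length.out = dimension)
  width <- 5 * sqrt(1 / min(k)) + 1
  energy <- function(X) {
    X <- as_cv_matrix(X, dimension)
    0.5 * as.numeric(sweep(X, 2, cen)^2 %*% k) + offset
  }
  gradient <- function(X) {
    X <- as_cv_matrix(X, dimension)
    sweep(sweep(X, 2, cen), 2, k, "*")
  }
  potential(energy, gradient, dimension, masses = masses,
            label = sprintf("harmonic(k=%s)", paste(signif(k, 4), collapse = ",")),
            box = cbind(cen - width, cen + width))
}

#' Symmetric 1-D double well
#'
#' V(x) = barrier * ((x / halfwidth)^2 - 1)^2, with minima at +- halfwidth and
#' a barrier of height `barrier` at x = 0.
#'
#' @param barrier barrier height (kcal/mol).
#' @param halfwidth distance of each minimum from the origin (Angstrom).
#' @param masses coordinate mass (amu).
#' @return a 1-D [potential()].
#' @export
double_well_potential <- function(barrier = 3, halfwidth = 1, masses = 1) {
  if (barrier <= 0 || halfwidth <= 0) stop("barrier and halfwidth must be positive")
  energy <- function(X) {
    x <- as_cv_matrix(X, 1)[, 1]
    barrier * ((x / halfwidth)^2 - 1)^2
  }
  gradient <- function(X) {
    x <- as_cv_matrix(X, 1)[, 1]
    matrix(barrier * 4 * x * ((x / halfwidth)^2 - 1) / halfwidth^2, ncol = 1)
  }
  potential(energy, gradient, 1, masses = masses,
            label = sprintf("double-well(h=%g)", barrier),
            box = matrix(c(-2.2 * halfwidth, 2.2 * halfwidth), 1))
}
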