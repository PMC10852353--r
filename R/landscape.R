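#' Stationary-point specification for a reaction landscape
#'
#' An ordered table of stationary free energies along a reaction path:
#' alternating minima and saddles, starting and ending at minima, as printed in
#' stationary-structure tables of free-energy studies. Energies are relative to
#' the declared zero reference, which may be one of the listed states (its
#' energy must then be 0) or an external reference state (e.g. the Michaelis
#' complex for a stage whose reactant already includes a preparation cost).
#'
#' @param label character vector of state labels.
#' @param kind "minimum" or "saddle" for each state.
#' @param free_energy free energies in kcal/mol relative to `zero_reference`.
#' @param zero_reference label of the zero-reference state.
#' @return a `stationary_spec` (data.frame with attribute `zero_reference`).
#' @export
#' @examples
#' stationary_spec(c("A", "TS", "B"), c("minimum", "saddle", "minimum"),
#'                 c(0, 5, -2), zero_reference = "A")
stationary_spec <- function(label, kind, free_energy, zero_reference) {
  n <- length(label)
  if (length(kind) != n || length(free_energy) != n) {
    stop("label, kind and free_energy must have equal length")
  }
  if (anyDuplicated(label)) stop("state labels must be unique")
  kind <- match.arg(kind, c("minimum", "saddle"), several.ok = TRUE)
  if (kind[1] != "minimum" || kind[n] != "minimum") {
    stop("a stationary spec must start and end with a minimum")
  }
  expected <- rep(c("minimum", "saddle"), length.out = n)
  if (!all(kind == expected)) {
    stop("stationary kinds must alternate minimum/saddle/minimum/...")
  }
  sad <- which(kind == "saddle")
  bad <- sad[free_energy[sad] <= free_energy[sad - 1] |
               free_energy[sad] <= free_energy[sad + 1]]
  if (length(bad)) {
    stop(sprintf("saddle(s) %s not above both flanking minima",
                 paste(label[bad], collapse = ", ")))
  }
  if (zero_reference %in% label) {
    if (abs(free_energy[match(zero_reference, label)]) > 1e-9) {
      stop("the zero-reference state must have free energy 0")
    }
  }
  out <- data.frame(label = label, kind = kind, free_energy = free_energy,
                    stringsAsFactors = FALSE)
  attr(out, "zero_reference") <- zero_reference
  class(out) <- c("stationary_spec", "data.frame")
  out
}

#' Read / write a stationary spec as CSV
#'
#' The CSV has columns `label,kind,free_energy`.
#'
#' @param file path to a CSV file.
#' @param zero_reference zero-reference label (see [stationary_spec()]).
#' @return [read_stationary_spec()] returns a `stationary_spec`.
#' @export
read_stationary_spec <- function(file, zero_reference) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("label", "kind", "free_energy")
  if (!all(need %in% names(d))) stop("CSV must have columns label,kind,free_energy")
  stationary_spec(d$label, d$kind, d$free_energy, zero_reference = zero_reference)
}

#' @rdname read_stationary_spec
#' @param spec a `stationary_spec`.
#' @export
write_stationary_spec <- function(spec, file) {
  utils::write.csv(as.data.frame(spec)[c("label", "kind", "free_energy")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Build a calibrated multi-basin reaction landscape
#'
#' Embeds a curve in CV space with stationary stations at equally spaced
#' arc-length positions and constructs a potential whose restriction to the
#' curve passes exactly through the prescribed free energies with zero
#' tangential derivative at every station (cubic Hermite interpolation with
#' clamped zero slopes), plus uniform harmonic confinement transverse to the
#' curve. Because the transverse stiffness is uniform, the exact PMF along the
#' curve equals the prescribed profile plus an additive constant, independent
#' of `transverse_k` (transverse-entropy cancellation).
#'
#' Beyond the first/last station the longitudinal profile continues as a
#' confining quadratic wall so the potential is bounded below on any box.
#'
#' @param spec a [stationary_spec()].
#' @param dimension embedding dimension (>= 2 for the default geometries; 1 is
#'   allowed with `geometry = "line"` for purely longitudinal fixtures).
#' @param transverse_k uniform transverse stiffness (kcal/mol/A^2, > 0).
#' @param geometry `"line"` (straight segment, stations equally spaced) or
#'   `"sine"` (half-wave sinusoidal bend in the first two coordinates, to
#'   exercise path curvature).
#' @param station_spacing arc spacing between stations (Angstrom).
#' @param origin curve start point.
#' @param direction unit direction of the line geometry (normalised
#'   internally; the sine geometry always bends coordinate 2 along 1).
#' @param bend_amplitude amplitude of the sinusoidal bend (Angstrom).
#' @param masses per-coordinate masses (amu).
#' @param wall_k stiffness of the longitudinal end walls.
#' @return a [potential()] with attributes `stations` (station coordinates),
#'   `station_t` (longitudinal positions), `spec`, `geometry`, `transverse_k`.
#' @export
make_reaction_landscape <- function(spec, dimension = 2, transverse_k = 50,
                                    geometry = c("line", "sine"),
                                    station_spacing = 1,
                                    origin = rep(0, dimension),
                                    direction = c(1, rep(0, dimension - 1)),
                                    bend_amplitude = 0.5,
                                    masses = rep(1, dimension),
                                    wall_k = transverse_k) {
  if (!inherits(spec, "stationary_spec")) stop("spec must be a stationary_spec")
  geometry <- match.arg(geometry)
  if (transverse_k <= 0) stop("transverse_k must be positive")
  if (dimension < 1 || (geometry == "sine" && dimension < 2)) {
    stop("dimension too small for the requested geometry")
  }
  m <- nrow(spec)
  if (m == 1 && geometry == "sine") stop("sine geometry needs >= 2 stations")
  y <- spec$free_energy
  t_st <- (seq_len(m) - 1) * station_spacing
  L <- t_st[m]

  # clamped-slope Hermite profile through the station energies
  f_of <- function(t) {
    v <- numeric(length(t))
    lo <- t < 0; hi <- t > L; mid <- !(lo | hi)
    if (m == 1) {
      return(y[1] + 0.5 * wall_k * t^2)
    }
    if (any(mid)) {
      tm <- t[mid]
      idx <- pmin(pmax(findInterval(tm, t_st), 1L), m - 1L)
      u <- (tm - t_st[idx]) / station_spacing
      v[mid] <- y[idx] + (y[idx + 1] - y[idx]) * u * u * (3 - 2 * u)
    }
    v[lo] <- y[1] + 0.5 * wall_k * t[lo]^2
    v[hi] <- y[m] + 0.5 * wall_k * (t[hi] - L)^2
    v
  }
  fp_of <- function(t) {
    v <- numeric(length(t))
    lo <- t < 0; hi <- t > L; mid <- !(lo | hi)
    if (m == 1) {
      return(wall_k * t)
    }
    if (any(mid)) {
      tm <- t[mid]
      idx <- pmin(pmax(findInterval(tm, t_st), 1L), m - 1L)
      u <- (tm - t_st[idx]) / station_spacing
      v[mid] <- (y[idx + 1] - y[idx]) * 6 * u * (1 - u) / station_spacing
    }
    v[lo] <- wall_k * t[lo]
    v[hi] <- wall_k * (t[hi] - L)
    v
  }

  if (geometry == "line") {
    u <- direction / sqrt(sum(direction^2))
    energy <- function(X) {
      X <- as_cv_matrix(X, dimension)
      D <- sweep(X, 2, origin)
      tc <- as.numeric(D %*% u)
      Z <- D - tcrossprod(tc, u)
      f_of(tc) + 0.5 * transverse_k * rowSums(Z^2)
    }
    gradient <- function(X) {
      X <- as_cv_matrix(X, dimension)
      D <- sweep(X, 2, origin)
      tc <- as.numeric(D %*% u)
      Z <- D - tcrossprod(tc, u)
      tcrossprod(fp_of(tc), u) + transverse_k * Z
    }
    stations <- sweep(tcrossprod(t_st, u), 2, origin, "+")
  } else {
    amp <- bend_amplitude
    psi <- function(t) amp * sin(pi * pmin(pmax(t, 0), L) / L)
    psip <- function(t) ifelse(t < 0 | t > L, 0, amp * pi / L * cos(pi * t / L))
    energy <- function(X) {
      X <- as_cv_matrix(X, dimension)
      tc <- X[, 1] - origin[1]
      w <- X[, 2] - origin[2] - psi(tc)
      rest <- if (dimension > 2) {
        rowSums(sweep(X[, -(1:2), drop = FALSE], 2, origin[-(1:2)])^2)
      } else 0
      f_of(tc) + 0.5 * transverse_k * (w^2 + rest)
    }
    gradient <- function(X) {
      X <- as_cv_matrix(X, dimension)
      tc <- X[, 1] - origin[1]
      w <- X[, 2] - origin[2] - psi(tc)
      G <- matrix(0, nrow(X), dimension)
      G[, 1] <- fp_of(tc) - transverse_k * w * psip(tc)
      G[, 2] <- transverse_k * w
      if (dimension > 2) {
        G[, -(1:2)] <- transverse_k * sweep(X[, -(1:2), drop = FALSE], 2,
                                            origin[-(1:2)])
      }
      G
    }
    stations <- matrix(rep(origin, each = m), m, dimension)
    stations[, 1] <- origin[1] + t_st
    stations[, 2] <- origin[2] + psi(t_st)
  }

  pad <- 1.5 + 3 * sqrt(kBT(1000) / transverse_k)
  box <- cbind(apply(stations, 2, min) - pad, apply(stations, 2, max) + pad)
  pot <- potential(energy, gradient, dimension, masses = masses,
                   label = sprintf("landscape[%s,%s]", geometry,
                                   attr(spec, "zero_reference")),
                   box = box)
  attr(pot, "stations") <- stations
  attr(pot, "station_t") <- t_st
  attr(pot, "spec") <- spec
  attr(pot, "geometry") <- geometry
  attr(pot, "transverse_k") <- transverse_k
  pot
}
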