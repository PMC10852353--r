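#' Build a path collective variable from a converged string
#'
#' Stores the string nodes together with their cumulative mass-weighted arc
#' lengths; the path CV s of a node i is L_i / L_total, so s runs from 0 at
#' the reactant node to 1 at the product node.
#'
#' @param x a converged `string_state` (see [run_string()]) or an N x D node
#'   matrix.
#' @param metric_masses per-CV masses defining the metric (taken from the
#'   string state when available).
#' @param override build from an unconverged string (error otherwise).
#' @return a `path_cv` with fields `nodes`, `metric_masses`, `arc_lengths`
#'   (cumulative, starting at 0), `total_length`, `s_nodes`.
#' @export
build_path <- function(x, metric_masses = NULL, override = FALSE) {
  if (inherits(x, "string_state")) {
    if (!isTRUE(x$converged) && !override) {
      stop("string not converged; pass override = TRUE to build anyway")
    }
    nodes <- x$nodes
    if (is.null(metric_masses)) metric_masses <- x$metric_masses
  } else {
    nodes <- as.matrix(x)
    if (is.null(metric_masses)) metric_masses <- rep(1, ncol(nodes))
  }
  if (nrow(nodes) < 2) stop("a path needs at least two nodes")
  Y <- mass_weight(nodes, metric_masses)
  seg <- sqrt(rowSums(diff(Y)^2))
  if (any(seg <= 0)) stop("consecutive path nodes must be distinct")
  arc <- c(0, cumsum(seg))
  structure(list(nodes = nodes, metric_masses = metric_masses,
                 arc_lengths = arc, total_length = arc[length(arc)],
                 s_nodes = arc / arc[length(arc)]),
            class = "path_cv")
}

#' @export
print.path_cv <- function(x, ...) {
  cat(sprintf("<path_cv> %d nodes, %d CV(s), metric length %.4g amu^1/2 A\n",
              nrow(x$nodes), ncol(x$nodes), x$total_length))
  invisible(x)
}

mass_weight <- function(X, masses) {
  sweep(X, 2, sqrt(rep(masses, length.out = ncol(X))), "*")
}

#' Extend a path beyond its terminal nodes
#'
#' Prepends/appends nodes continuing the terminal segments by a metric length
#' `pad`, so that terminal basins fall at interior s values during umbrella
#' sampling (projection onto a path clamps s at the ends, which piles density
#' into the boundary bins when a free-energy minimum sits exactly there).
#'
#' @param path a `path_cv`.
#' @param pad extension length at each end (amu^1/2 Angstrom).
#' @return a new `path_cv`.
#' @export
extend_path <- function(path, pad) {
  if (pad <= 0) return(path)
  nodes <- path$nodes
  Y <- mass_weight(nodes, path$metric_masses)
  n <- nrow(Y)
  u1 <- Y[1, ] - Y[2, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- Y[n, ] - Y[n - 1, ]; u2 <- u2 / sqrt(sum(u2^2))
  msq <- sqrt(rep(path$metric_masses, length.out = ncol(Y)))
  ext <- rbind((Y[1, ] + pad * u1) / msq, nodes, (Y[n, ] + pad * u2) / msq)
  build_path(ext, metric_masses = path$metric_masses)
}

#' Point on a path at a given s
#'
#' Linear interpolation along the piecewise-linear path at normalised arc
#' length `s` (clamped to [0, 1]).
#'
#' @param path a `path_cv`.
#' @param s scalar or vector of s values.
#' @return a length(s) x D matrix of CV coordinates.
#' @export
path_point <- function(path, s) {
  s <- pmin(pmax(s, 0), 1)
  tgt <- s * path$total_length
  arc <- path$arc_lengths
  idx <- pmin(pmax(findInterval(tgt, arc), 1L), nrow(path$nodes) - 1L)
  frac <- (tgt - arc[idx]) / (arc[idx + 1] - arc[idx])
  path$nodes[idx, , drop = FALSE] +
    frac * (path$nodes[idx + 1, , drop = FALSE] - path$nodes[idx, , drop = FALSE])
}

#' Project configurations onto a path CV
#'
#' Nearest point on the piecewise-linear path in the mass-weighted metric.
#' s is the normalised arc length of that point (clamped to [0, 1]); z is the
#' metric distance to it (amu^1/2 Angstrom). Ties between segments are
#' resolved to the lower segment index.
#'
#' @param x configuration vector or n x d matrix.
#' @param path a `path_cv`.
#' @return list with `s`, `z`, `segment` (index used per row), `grad_s`
#'   (n x d gradient of s with respect to x, constant within a segment) and
#'   `point` (closest path points, n x d).
#' @export
path_project <- function(x, path) {
  d <- ncol(path$nodes)
  X <- as_cv_matrix(x, d)
  n <- nrow(X)
  msq <- sqrt(rep(path$metric_masses, length.out = d))
  Y <- sweep(X, 2, msq, "*")
  Nd <- sweep(path$nodes, 2, msq, "*")
  m <- nrow(Nd) - 1L
  S <- diff(Nd)
  len <- sqrt(rowSums(S^2))
  U <- S / len
  # projection length of (y - n_j) on each segment direction
  Tm <- Y %*% t(U) - matrix(rowSums(Nd[-(m + 1L), , drop = FALSE] * U),
                            n, m, byrow = TRUE)
  Tc <- pmin(pmax(Tm, 0), matrix(len, n, m, byrow = TRUE))
  YY <- rowSums(Y^2)
  NN <- rowSums(Nd[-(m + 1L), , drop = FALSE]^2)
  D2 <- YY + matrix(NN, n, m, byrow = TRUE) -
    2 * Y %*% t(Nd[-(m + 1L), , drop = FALSE]) - 2 * Tc * Tm + Tc^2
  D2 <- pmax(D2, 0)
  jstar <- max.col(-D2, ties.method = "first")
  pick <- cbind(seq_len(n), jstar)
  s <- (path$arc_lengths[jstar] + Tc[pick]) / path$total_length
  s <- pmin(pmax(s, 0), 1)
  z <- sqrt(D2[pick])
  grad_s <- sweep(U[jstar, , drop = FALSE], 2, msq, "*") / path$total_length
  point <- path$nodes[jstar, , drop = FALSE] +
    (Tc[pick] / len[jstar]) *
    (path$nodes[jstar + 1L, , drop = FALSE] - path$nodes[jstar, , drop = FALSE])
  list(s = s, z = z, segment = jstar, grad_s = grad_s, point = point)
}
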