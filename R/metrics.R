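#' Collective-variable time series
#'
#' A uniformly spaced multivariate time series of CV values, the container for
#' trajectory descriptors (RMSF, RMSD, 2-D state densities).
#'
#' @param values n x d matrix (or vector) of per-frame CV values.
#' @param time optional frame times (ps); must be uniformly spaced. Defaults
#'   to (0, dt, 2 dt, ...).
#' @param dt frame spacing in ps when `time` is not given.
#' @param labels optional coordinate labels.
#' @param periodic logical per coordinate: TRUE marks an angular coordinate in
#'   degrees with period 360 (wrapped into [-180, 180) by the descriptors).
#' @return a `cv_series`.
#' @export
cv_series <- function(values, time = NULL, dt = 1, labels = NULL,
                      periodic = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  n <- nrow(values); d <- ncol(values)
  if (is.null(time)) time <- (seq_len(n) - 1) * dt
  if (length(time) != n) stop("time length must match the number of frames")
  if (n >= 3) {
    steps <- diff(time)
    if (any(abs(steps - steps[1]) > 1e-9 * max(abs(steps[1]), 1))) {
      stop("time spacing must be uniform")
    }
  }
  if (anyNA(values)) stop("missing frames are not allowed")
  if (is.null(labels)) labels <- paste0("cv", seq_len(d))
  if (is.null(periodic)) periodic <- rep(FALSE, d)
  colnames(values) <- labels
  structure(list(time = time, values = values, labels = labels,
                 periodic = rep(periodic, length.out = d)),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("<cv_series> %d frames x %d coordinate(s) [%s], dt = %g ps\n",
              nrow(x$values), ncol(x$values), paste(x$labels, collapse = ", "),
              if (nrow(x$values) > 1) x$time[2] - x$time[1] else NA))
  invisible(x)
}

#' Write / read a CV series as CSV
#'
#' Columns `t, <label1>, <label2>, ...`; values written with 17 significant
#' digits so descriptors are reproducible bit-exactly from the persisted file.
#'
#' @param series a [cv_series()].
#' @param file path.
#' @export
write_cv_series <- function(series, file) {
  d <- data.frame(t = sprintf("%.17g", series$time))
  for (j in seq_len(ncol(series$values))) {
    d[[series$labels[j]]] <- sprintf("%.17g", series$values[, j])
  }
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cv_series
#' @param periodic passed through to [cv_series()].
#' @export
read_cv_series <- function(file, periodic = NULL) {
  d <- utils::read.csv(file)
  cv_series(as.matrix(d[-1]), time = d$t, labels = names(d)[-1],
            periodic = periodic)
}

#' Root-mean-square fluctuation per coordinate
#'
#' RMSF_j = sqrt(mean_t (x_j(t) - mean_t x_j)^2).
#'
#' @param series a [cv_series()] with at least 2 frames.
#' @return named numeric vector, one value per coordinate.
#' @export
rmsf <- function(series) {
  X <- series$values
  if (nrow(X) < 2) stop("RMSF needs at least 2 frames")
  mu <- colMeans(X)
  out <- sqrt(colMeans(sweep(X, 2, mu)^2))
  names(out) <- series$labels
  out
}

#' Weighted CV-space RMSD to a reference frame
#'
#' Per-frame distance sqrt(sum_j w_j (x_j - ref_j)^2); no superposition is
#' performed (these are CV-space, not Cartesian, coordinates). With
#' mass-weights, the result is in amu^1/2 Angstrom.
#'
#' @param series a [cv_series()].
#' @param reference reference CV vector (e.g. the first frame).
#' @param weights per-coordinate weights (default 1).
#' @return numeric vector, one distance per frame.
#' @export
rmsd_to_reference <- function(series, reference, weights = NULL) {
  X <- series$values
  d <- ncol(X)
  if (length(reference) != d) stop("reference dimension mismatch")
  if (is.null(weights)) weights <- rep(1, d)
  if (length(weights) != d) stop("weight length mismatch")
  sqrt(as.numeric(sweep(X, 2, reference)^2 %*% weights))
}

wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' 2-D state-density map of two CVs
#'
#' Normalised 2-D histogram of two coordinates plus the time-resolved track,
#' the generic form of distance-vs-dihedral state maps. Coordinates flagged
#' periodic in the series are wrapped into [-180, 180) and binned on that
#' fixed range.
#'
#' @param series a [cv_series()].
#' @param coord_x,coord_y coordinate names or indices.
#' @param bins number of bins per axis (>= 2).
#' @return list with `density` (bins x bins matrix summing to 1), `x_breaks`,
#'   `y_breaks`, `x_mids`, `y_mids` and `track` (data.frame t, x, y).
#' @export
state_density_2d <- function(series, coord_x = 1, coord_y = 2, bins = 50) {
  bins <- as.integer(bins)
  if (bins < 2) stop("bins must be >= 2")
  ix <- if (is.character(coord_x)) match(coord_x, series$labels) else coord_x
  iy <- if (is.character(coord_y)) match(coord_y, series$labels) else coord_y
  if (is.na(ix) || is.na(iy)) stop("both coordinates must be present")
  get <- function(i) {
    v <- series$values[, i]
    if (series$periodic[i]) wrap_angle(v) else v
  }
  x <- get(ix); y <- get(iy)
  brk <- function(v, per) {
    if (per) seq(-180, 180, length.out = bins + 1) else {
      r <- range(v)
      if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
      seq(r[1], r[2], length.out = bins + 1)
    }
  }
  xb <- brk(x, series$periodic[ix]); yb <- brk(y, series$periodic[iy])
  bi <- function(v, b) pmin(pmax(findInterval(v, b, all.inside = TRUE), 1L),
                            bins)
  h <- table(factor(bi(x, xb), levels = seq_len(bins)),
             factor(bi(y, yb), levels = seq_len(bins)))
  dens <- matrix(as.numeric(h), bins, bins) / length(x)
  list(density = dens, x_breaks = xb, y_breaks = yb,
       x_mids = (xb[-1] + xb[-(bins + 1)]) / 2,
       y_mids = (yb[-1] + yb[-(bins + 1)]) / 2,
       track = data.frame(t = series$time, x = x, y = y))
}
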