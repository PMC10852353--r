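#' Langevin sampler configuration
#'
#' Defaults follow the study conditions of the enzyme simulations this package
#' emulates: 310 K, friction 2.0 ps^-1, 1 fs timestep. Burn-in defaults to 10%
#' of the run.
#'
#' @param n_steps number of integration steps (positive integer).
#' @param temperature temperature in K.
#' @param friction collision frequency in ps^-1.
#' @param timestep timestep in fs.
#' @param burn_in steps discarded before accumulating (default 10% of
#'   `n_steps`, must be < `n_steps`).
#' @param seed integer seed.
#' @param masses optional per-coordinate masses (amu); defaults to the
#'   potential's masses at sampling time.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(n_steps, temperature = 310, friction = 2,
                           timestep = 1, burn_in = NULL, seed = 1,
                           masses = NULL, thin = 1L) {
  n_steps <- as.integer(n_steps)
  if (n_steps <= 0) stop("n_steps must be positive")
  if (temperature <= 0 || friction <= 0 || timestep <= 0) {
    stop("temperature, friction and timestep must be positive")
  }
  if (is.null(burn_in)) burn_in <- as.integer(floor(0.1 * n_steps))
  burn_in <- as.integer(burn_in)
  if (burn_in < 0 || burn_in >= n_steps) stop("burn_in must be in [0, n_steps)")
  structure(list(n_steps = n_steps, temperature = temperature,
                 friction = friction, timestep = timestep, burn_in = burn_in,
                 seed = as.integer(seed), masses = masses,
                 thin = as.integer(thin)),
            class = "sampler_config")
}

#' Harmonic restraint
#'
#' Either a full-vector restraint k/2 |x - center|^2 or a path-coordinate
#' restraint k/2 (s(x) - center)^2 where s is the path CV of `path`.
#'
#' @param center CV vector (full coupling) or scalar s in [0, 1] (path
#'   coupling).
#' @param stiffness restraint stiffness, >= 0 (kcal/mol/A^2, or kcal/mol per
#'   unit s^2 for path coupling).
#' @param coupling `"vector"` or `"path"`.
#' @param path a [build_path()] object (required for path coupling).
#' @return a `restraint`.
#' @export
harmonic_restraint <- function(center, stiffness, coupling = c("vector", "path"),
                               path = NULL) {
  coupling <- match.arg(coupling)
  if (any(stiffness < 0)) stop("stiffness must be >= 0")
  if (coupling == "path" && is.null(path)) stop("path coupling requires a path")
  structure(list(center = center, stiffness = stiffness, coupling = coupling,
                 path = path),
            class = "restraint")
}

# --- internal multi-walker BAOAB engine -------------------------------------
#
# Steps n walkers (rows of X0) in lockstep under a shared gradient function.
# grad_fn(X) returns the full force gradient (potential + biases) as an
# n x d matrix. observe_fn(X) maps positions to the recorded observable
# (numeric vector, one value per walker, or an n x d matrix when record_mean
# is used on positions). exchange_fn, if given, is called every exchange_every
# steps and may permute rows of X and V.
#
# The caller owns the RNG state (wrap in with_seed()).
lengine <- function(grad_fn, X0, masses, config,
                    observe_fn = NULL, record = c("mean", "series"),
                    exchange_fn = NULL, exchange_every = 0L,
                    check_every = 100L) {
  record <- match.arg(record)
  X <- X0
  n <- nrow(X); d <- ncol(X)
  kt <- kBT(config$temperature)
  dt <- config$timestep / akma_fs
  gam <- config$friction * akma_fs * 1e-3
  c1 <- exp(-gam * dt)
  mrow <- rep(masses, length.out = d)
  Msd <- matrix(sqrt(kt / mrow) * sqrt(1 - c1^2), n, d, byrow = TRUE)
  Hm <- matrix(dt / (2 * mrow), n, d, byrow = TRUE)
  Hdt <- dt / 2
  V <- matrix(stats::rnorm(n * d), n, d) * matrix(sqrt(kt / mrow), n, d,
                                                  byrow = TRUE)
  G <- grad_fn(X)
  n_post <- config$n_steps - config$burn_in
  n_rec <- n_post %/% config$thin
  if (!is.null(observe_fn)) {
    probe <- observe_fn(X)
    if (record == "series") {
      series <- matrix(NA_real_, n_rec, length(probe))
    } else {
      osum <- probe * 0
    }
  }
  rec <- 0L
  n_obs <- 0L
  for (step in seq_len(config$n_steps)) {
    V <- V - Hm * G
    X <- X + Hdt * V
    V <- c1 * V + Msd * matrix(stats::rnorm(n * d), n, d)
    X <- X + Hdt * V
    G <- grad_fn(X)
    V <- V - Hm * G
    if (exchange_every > 0L && step %% exchange_every == 0L) {
      sw <- exchange_fn(X, V, step)
      X <- sw$X; V <- sw$V
    }
    if (step > config$burn_in) {
      k <- step - config$burn_in
      if (k %% config$thin == 0L) {
        obs <- observe_fn(X)
        if (record == "series") {
          rec <- rec + 1L
          series[rec, ] <- obs
        } else {
          osum <- osum + obs
          n_obs <- n_obs + 1L
        }
      }
    }
    if (step %% check_every == 0L && !all(is.finite(X))) {
      bad <- which(!is.finite(rowSums(X)))[1]
      stop(sprintf("non-finite position encountered at step %d, walker %d: [%s]",
                   step, bad, paste(signif(X[bad, ], 4), collapse = ", ")))
    }
  }
  if (!all(is.finite(X))) stop("non-finite position at end of run")
  if (is.null(observe_fn)) return(list(X = X))
  if (record == "series") list(X = X, series = series[seq_len(rec), , drop = FALSE])
  else list(X = X, mean = osum / n_obs)
}

# Gradient closure for a restraint (vector coupling); path coupling is handled
# where the projection is already computed.
restraint_gradient <- function(restr, X) {
  if (is.null(restr)) return(0)
  if (restr$coupling == "vector") {
    sweep(sweep(X, 2, restr$center), 2,
          rep(restr$stiffness, length.out = ncol(X)), "*")
  } else {
    pr <- path_project(X, restr$path)
    (restr$stiffness * (pr$s - restr$center)) * pr$grad_s
  }
}

restraint_energy <- function(restr, X) {
  if (is.null(restr)) return(0)
  if (restr$coupling == "vector") {
    0.5 * as.numeric(sweep(X, 2, restr$center)^2 %*%
                       rep(restr$stiffness, length.out = ncol(X)))
  } else {
    pr <- path_project(X, restr$path)
    0.5 * restr$stiffness * (pr$s - restr$center)^2
  }
}

#' Sample a potential with underdamped Langevin dynamics
#'
#' BAOAB-splitting Langevin integrator. Post-burn-in samples are Boltzmann
#' distributed for V + restraint at the configured temperature (up to the
#' usual O(dt^2) configurational bias, negligible at 1 fs for the stiffnesses
#' used here). Runs are exactly reproducible under `config$seed`.
#'
#' @param pot a [potential()].
#' @param restraint a [harmonic_restraint()] or `NULL`.
#' @param config a [sampler_config()].
#' @param x0 starting configuration (defaults to the restraint center, or the
#'   box center).
#' @return a list with `trajectory` (post-burn-in samples, matrix n x d),
#'   `mean_position`, and `mean_restraint_force` = stiffness * (mean_position -
#'   center) for vector restraints (`NULL` otherwise).
#' @export
langevin_sample <- function(pot, restraint = NULL, config, x0 = NULL) {
  d <- pot$dimension
  if (d < 1) stop("zero-dimension input")
  if (!is.null(restraint) && restraint$coupling == "vector" &&
      length(rep(restraint$center, length.out = d)) != d) {
    stop("restraint dimension mismatch")
  }
  if (is.null(x0)) {
    x0 <- if (!is.null(restraint) && restraint$coupling == "vector") {
      rep(restraint$center, length.out = d)
    } else if (!is.null(pot$box)) rowMeans(pot$box) else rep(0, d)
  }
  masses <- if (!is.null(config$masses)) config$masses else pot$masses
  grad_fn <- function(X) pot$gradient(X) + restraint_gradient(restraint, X)
  res <- with_seed(config$seed, {
    lengine(grad_fn, matrix(x0, 1, d), masses, config,
            observe_fn = function(X) as.numeric(X), record = "series")
  })
  traj <- res$series
  mp <- colMeans(traj)
  mrf <- if (!is.null(restraint) && restraint$coupling == "vector") {
    rep(restraint$stiffness, length.out = d) *
      (mp - rep(restraint$center, length.out = d))
  } else NULL
  list(trajectory = traj, mean_position = mp, mean_restraint_force = mrf,
       config = config)
}

#' Boltzmann-quadrature equilibrium average
#'
#' Deterministic dense-grid estimate of an equilibrium average
#' < observable > under exp(-V/kT) on a box (dimension <= 3). Serves as the
#' independent oracle against which stochastic sampling is validated. The
#' reported discretisation error is the change when the grid is coarsened by
#' a factor of two.
#'
#' @param pot a [potential()].
#' @param observable function(X) -> numeric(n); defaults to the identity on
#'   the first coordinate.
#' @param box d x 2 bounds (defaults to `pot$box`).
#' @param temperature temperature (K).
#' @param restraint optional [harmonic_restraint()] added to the energy.
#' @param n_grid grid points per coordinate (odd preferred).
#' @return the average, with attributes `error` (discretisation estimate) and
#'   `boundary_mass` (max boundary density / max density; a warning is issued
#'   above 1e-10).
#' @export
equilibrium_moment <- function(pot, observable = function(X) X[, 1],
                               box = pot$box, temperature = 310,
                               restraint = NULL, n_grid = 201) {
  d <- pot$dimension
  if (d > 3) stop("quadrature limited to dimension <= 3")
  if (is.null(box)) stop("a sampling box is required")
  box <- matrix(as.numeric(box), ncol = 2)
  beta <- 1 / kBT(temperature)
  eval_on <- function(ng) {
    grids <- lapply(seq_len(d), function(j) seq(box[j, 1], box[j, 2],
                                                length.out = ng))
    X <- as.matrix(expand.grid(grids))
    E <- pot$energy(X) + restraint_energy(restraint, X)
    w <- exp(-beta * (E - min(E)))
    on_boundary <- rowSums(sapply(seq_len(d), function(j) {
      X[, j] == box[j, 1] | X[, j] == box[j, 2]
    })) > 0
    list(val = sum(w * observable(X)) / sum(w),
         bmass = max(w[on_boundary]) / max(w))
  }
  fine <- eval_on(n_grid)
  coarse <- eval_on(max(11L, n_grid %/% 2L))
  if (fine$bmass > 1e-10) {
    warning(sprintf("box may be too small: boundary density %.3g of max",
                    fine$bmass))
  }
  structure(fine$val, error = abs(fine$val - coarse$val),
            boundary_mass = fine$bmass)
}
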