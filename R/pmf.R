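#' Place umbrella windows along a path CV with on-the-fly force constants
#'
#' Centers are equally spaced in s with interior placement,
#' c_i = (i - 1/2) / n. The initial stiffness k = 4 kT / ds^2 gives a biased
#' Gaussian of sd = ds/2 on a flat profile; after a pilot run each window's
#' stiffness is rescaled by (observed sd / target sd)^2 and clipped to
#' [0.25, 4] times the initial value, so the final production run yields a
#' near-homogeneous density of the reaction coordinate. Windows whose pilot
#' histogram is empty near their center are retried once at 4x stiffness.
#'
#' @param pot the [potential()] sampled.
#' @param path a [build_path()] path CV.
#' @param n_windows number of windows (>= 2; default 48).
#' @param temperature temperature (K).
#' @param pilot_steps steps of the pilot run per window.
#' @param seed integer seed.
#' @param friction,timestep Langevin parameters (see [sampler_config()]).
#' @return a `window_set` with calibrated `stiffness` (samples are filled by
#'   [umbrella_sample()]).
#' @export
place_windows <- function(pot, path, n_windows = 48, temperature = 310,
                          pilot_steps = 5000, seed = 1, friction = 2,
                          timestep = 1) {
  n_windows <- as.integer(n_windows)
  if (n_windows < 2) stop("n_windows must be >= 2")
  ds <- 1 / n_windows
  centers <- (seq_len(n_windows) - 0.5) * ds
  k0 <- rep(4 * kBT(temperature) / ds^2, n_windows)
  target_sd <- ds / 2
  cfg <- sampler_config(pilot_steps, temperature = temperature,
                        friction = friction, timestep = timestep,
                        seed = derive_seed(seed, 1L))
  run_pilot <- function(kv) {
    umbrella_run(pot, path, centers, kv, cfg)
  }
  S <- run_pilot(k0)
  occupied <- vapply(seq_len(n_windows), function(i) {
    any(abs(S[, i] - centers[i]) <= ds)
  }, logical(1))
  if (!all(occupied)) {
    k0[!occupied] <- k0[!occupied] * 4
    cfg$seed <- derive_seed(seed, 2L)
    S <- run_pilot(k0)
    occupied <- vapply(seq_len(n_windows), function(i) {
      any(abs(S[, i] - centers[i]) <= ds)
    }, logical(1))
    if (!all(occupied)) {
      stop(sprintf("empty pilot histogram in window(s) %s after stiffening",
                   paste(which(!occupied), collapse = ", ")))
    }
  }
  sd_obs <- apply(S, 2, stats::sd)
  fac <- pmin(4, pmax(0.25, (sd_obs / target_sd)^2))
  structure(list(centers = centers, stiffness = k0 * fac,
                 initial_stiffness = k0, pilot_sd = sd_obs,
                 samples = NULL, temperature = temperature,
                 range = c(0, 1), path = path),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  ns <- if (is.null(x$samples)) 0L else lengths(x$samples)[1]
  cat(sprintf("<window_set> %d windows on [%g, %g], %s samples/window\n",
              length(x$centers), x$range[1], x$range[2],
              if (ns) format(ns, big.mark = ",") else "no"))
  invisible(x)
}

# Lockstep biased sampling of all windows; returns an (n_samples x n_windows)
# matrix of s values. The gradient closure caches the projection so that the
# recorded observable reuses it.
umbrella_run <- function(pot, path, centers, stiffness, cfg) {
  n <- length(centers)
  X0 <- path_point(path, centers)
  last_s <- centers
  grad_fn <- function(X) {
    pr <- path_project(X, path)
    last_s <<- pr$s
    pot$gradient(X) + (stiffness * (pr$s - centers)) * pr$grad_s
  }
  masses <- if (!is.null(cfg$masses)) cfg$masses else path$metric_masses
  res <- with_seed(cfg$seed, {
    lengine(grad_fn, X0, masses, cfg,
            observe_fn = function(X) last_s, record = "series")
  })
  res$series
}

#' Production umbrella sampling over a window set
#'
#' Runs the Langevin sampler in every window (lockstep) with the calibrated
#' stiffnesses of [place_windows()] and stores the post-burn-in s series.
#'
#' @param pot,path as in [place_windows()].
#' @param windows a `window_set`.
#' @param n_steps production steps per window; the default gives 5e4
#'   post-burn-in samples.
#' @param burn_in discarded steps.
#' @param seed integer seed.
#' @param friction,timestep Langevin parameters.
#' @return the `window_set` with `samples` filled (a list of numeric vectors).
#' @export
umbrella_sample <- function(pot, path, windows, n_steps = 55000,
                            burn_in = 5000, seed = 1, friction = 2,
                            timestep = 1) {
  cfg <- sampler_config(n_steps, temperature = windows$temperature,
                        friction = friction, timestep = timestep,
                        burn_in = burn_in, seed = derive_seed(seed, 3L))
  S <- umbrella_run(pot, path, windows$centers, windows$stiffness, cfg)
  windows$samples <- lapply(seq_len(ncol(S)), function(i) S[, i])
  windows
}

# locate the zero-reference bin for a profile: "first_min" walks from s = 0
# and takes the minimum of the first basin (everything before the profile
# first rises `drop` above the running minimum); "global_min" takes the global
# minimum.
zero_reference_bin <- function(G, zero_reference, drop = 2) {
  ok <- which(is.finite(G))
  if (identical(zero_reference, "global_min")) return(ok[which.min(G[ok])])
  runmin <- cummin(ifelse(is.finite(G), G, Inf))
  above <- which(G - runmin >= drop & is.finite(G))
  last <- if (length(above)) above[1] else length(G)
  cand <- ok[ok <= last]
  cand[which.min(G[cand])]
}

#' WHAM reconstruction of the free-energy profile
#'
#' Standard self-consistent weighted-histogram solution over the window set,
#' iterated until the maximum change of the window free energies falls below
#' `tolerance` (relative to their magnitude). The profile is shifted so the
#' declared zero reference is 0.
#'
#' @param windows a sampled `window_set` (see [umbrella_sample()]); adjacent
#'   windows must overlap (shared support of at least one bin).
#' @param temperature temperature (K); defaults to the window set's.
#' @param n_bins number of histogram bins over the coordinate range.
#' @param tolerance convergence tolerance on the window free energies.
#' @param max_iter iteration cap (failure to converge is an error reporting
#'   the residual).
#' @param zero_reference `"first_min"` (default; the minimum of the first
#'   basin along s, i.e. the stage reactant), `"global_min"`, or a numeric s
#'   whose bin is used.
#' @param f_init optional warm-start window free energies.
#' @return a `pmf_profile`: data.frame with columns `s` (bin centers),
#'   `free_energy` (kcal/mol, zero at the reference; NA for empty bins) and
#'   `uncertainty` (filled by [pmf_error()]), with attributes `window_f`,
#'   `counts`, `temperature`, `breaks`, `zero_bin`, `iterations`.
#' @export
wham <- function(windows, temperature = windows$temperature, n_bins = 200,
                 tolerance = 1e-10, max_iter = 100000L,
                 zero_reference = "first_min", f_init = NULL) {
  if (is.null(windows$samples)) stop("windows carry no samples; run umbrella_sample()")
  rng <- windows$range
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  I <- length(windows$centers)
  counts <- vapply(windows$samples, function(s) {
    s <- pmin(pmax(s, rng[1]), rng[2])
    tabulate(pmin(pmax(findInterval(s, breaks, all.inside = TRUE), 1L),
                  n_bins), n_bins)
  }, numeric(n_bins))                     # n_bins x I
  for (i in seq_len(I - 1L)) {
    if (!any(counts[, i] > 0 & counts[, i + 1] > 0)) {
      stop(sprintf(
        "no histogram overlap between windows %d (c=%.4g) and %d (c=%.4g)",
        i, windows$centers[i], i + 1, windows$centers[i + 1]))
    }
  }
  fit <- wham_solve(counts, windows$centers, windows$stiffness, mids,
                    temperature, tolerance, max_iter, f_init)
  kt <- kBT(temperature)
  G <- -kt * log(fit$P)
  G[!is.finite(G)] <- NA_real_
  zb <- if (is.numeric(zero_reference)) {
    pmin(pmax(findInterval(zero_reference, breaks, all.inside = TRUE), 1L),
         n_bins)
  } else {
    zero_reference_bin(G, zero_reference)
  }
  G <- G - G[zb]
  out <- data.frame(s = mids, free_energy = G, uncertainty = NA_real_)
  attr(out, "window_f") <- fit$f
  attr(out, "counts") <- counts
  attr(out, "temperature") <- temperature
  attr(out, "breaks") <- breaks
  attr(out, "zero_bin") <- zb
  attr(out, "zero_reference") <- zero_reference
  attr(out, "iterations") <- fit$iterations
  attr(out, "windows_meta") <- windows[c("centers", "stiffness", "range",
                                         "temperature")]
  class(out) <- c("pmf_profile", "data.frame")
  out
}

# Core WHAM solver; counts is n_bins x I.
#
# Self-consistent iteration converges geometrically with a rate that
# approaches 1 when adjacent windows overlap thinly (narrow stiff windows),
# which can leave errors of several tenths of kcal/mol after 1e5 sweeps.
# The window free energies are therefore obtained by minimising the convex
# WHAM negative log-likelihood directly (L-BFGS with analytic gradient,
# warm-startable), then polished by self-consistent sweeps until the stated
# tolerance is met.
wham_solve <- function(counts, centers, stiffness, mids, temperature,
                       tolerance, max_iter, f_init = NULL) {
  kt <- kBT(temperature)
  I <- length(centers)
  B <- length(mids)
  W <- 0.5 * outer(mids, centers, function(s, c) (s - c)^2) *
    matrix(stiffness, B, I, byrow = TRUE)
  C <- exp(-W / kt)                        # B x I bias factors
  Ni <- colSums(counts)
  M <- rowSums(counts)
  f <- if (is.null(f_init)) numeric(I) else f_init - f_init[1]

  if (I > 1) {
    A <- matrix(log(Ni), B, I, byrow = TRUE) - W / kt   # ln(N_i) - w_il/kT
    nll <- function(g1) {
      S <- A + matrix(c(0, g1), B, I, byrow = TRUE)
      m <- do.call(pmax, as.data.frame(S))
      lse <- m + log(rowSums(exp(S - m)))
      sum(M * lse) - sum(Ni[-1] * g1)
    }
    nll_grad <- function(g1) {
      S <- A + matrix(c(0, g1), B, I, byrow = TRUE)
      m <- do.call(pmax, as.data.frame(S))
      E <- exp(S - m)
      soft <- E / rowSums(E)
      as.numeric(crossprod(soft, M))[-1] - Ni[-1]
    }
    opt <- stats::optim(f[-1] / kt, nll, nll_grad, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10))
    f <- kt * c(0, opt$par)
  }

  resid <- Inf
  for (it in seq_len(max_iter)) {
    wgt <- Ni * exp((f - max(f)) / kt)   # shift cancels in the re-anchored f
    denom <- as.numeric(C %*% wgt)
    P <- ifelse(denom > 0, M / denom, 0)
    Z <- as.numeric(crossprod(C, P))
    f_new <- -kt * log(Z)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tolerance * max(1, max(abs(f)))) {
      P <- P / sum(P)
      return(list(f = f, P = P, iterations = it))
    }
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
               max_iter, resid))
}

#' Block-bootstrap uncertainty of a WHAM profile
#'
#' Splits each window's s series into `n_blocks` contiguous blocks, resamples
#' blocks with replacement, re-solves WHAM (warm-started from the full-data
#' solution) and reports the per-bin standard deviation across resamples, with
#' every resampled profile re-zeroed by the profile's own reference rule.
#'
#' @param windows the sampled `window_set` used for `profile`.
#' @param profile the [wham()] profile whose uncertainty is sought.
#' @param n_resamples number of bootstrap resamples (>= 2).
#' @param n_blocks contiguous blocks per window (>= 2).
#' @param seed integer seed (fixed seed reproduces identical uncertainties).
#' @param tolerance WHAM tolerance for the resamples.
#' @return the profile with its `uncertainty` column filled (attribute
#'   `bootstrap` holds the resample matrix dimensions and seed).
#' @export
pmf_error <- function(windows, profile, n_resamples = 100, n_blocks = 20,
                      seed = 1, tolerance = 1e-8) {
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  if (n_blocks < 2) stop("need at least 2 blocks per window")
  if (any(lengths(windows$samples) < n_blocks)) {
    stop("fewer samples than blocks in some window")
  }
  breaks <- attr(profile, "breaks")
  mids <- profile$s
  B <- length(mids)
  temperature <- attr(profile, "temperature")
  f0 <- attr(profile, "window_f")
  zr <- attr(profile, "zero_reference")
  kt <- kBT(temperature)
  rng <- windows$range
  blocks <- lapply(windows$samples, function(s) {
    idx <- cut(seq_along(s), n_blocks, labels = FALSE)
    split(s, idx)
  })
  Gm <- with_seed(derive_seed(seed, 97L), {
    vapply(seq_len(n_resamples), function(r) {
      counts <- vapply(blocks, function(bl) {
        s <- unlist(bl[sample.int(n_blocks, n_blocks, replace = TRUE)],
                    use.names = FALSE)
        s <- pmin(pmax(s, rng[1]), rng[2])
        tabulate(pmin(pmax(findInterval(s, breaks, all.inside = TRUE), 1L), B),
                 B)
      }, numeric(B))
      fit <- wham_solve(counts, windows$centers, windows$stiffness, mids,
                        temperature, tolerance, 100000L, f_init = f0)
      G <- -kt * log(fit$P)
      G[!is.finite(G)] <- NA_real_
      zb <- if (is.numeric(zr)) attr(profile, "zero_bin") else {
        zero_reference_bin(G, zr)
      }
      G - G[zb]
    }, numeric(B))
  })
  profile$uncertainty <- apply(Gm, 1, stats::sd, na.rm = TRUE)
  attr(profile, "bootstrap") <- list(n_resamples = n_resamples,
                                     n_blocks = n_blocks, seed = seed)
  profile
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat(sprintf("<pmf_profile> %d bins on [%.3g, %.3g]; range %.3g .. %.3g kcal/mol%s\n",
              nrow(x), min(x$s), max(x$s), min(x$free_energy[ok]),
              max(x$free_energy[ok]),
              if (all(is.na(x$uncertainty))) "" else
                sprintf("; median err %.3g", stats::median(x$uncertainty,
                                                           na.rm = TRUE))))
  invisible(x)
}

# moving-average smoothing with shrinking window at the edges
smooth_profile <- function(g, w) {
  if (w <= 1) return(g)
  n <- length(g)
  half <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(g[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Extract the stationary-point table from a PMF profile
#'
#' Local minima and maxima of the (optionally moving-average smoothed)
#' profile, pruned so that every adjacent minimum/maximum pair differs by at
#' least `min_prominence`; endpoints are always retained. Energies are
#' reported on the profile's zero reference.
#'
#' @param profile a [wham()] `pmf_profile` (or any data.frame with columns
#'   `s`, `free_energy`, optional `uncertainty`).
#' @param smoothing_window moving-average width in bins (1 = no smoothing).
#' @param min_prominence minimum amplitude of retained features (kcal/mol).
#' @param labels optional state labels (length must match the number of
#'   extracted points).
#' @param trim_boundary_maxima drop a leading/trailing maximum that sits on
#'   the first or last profile bin; those are confinement-wall artifacts when
#'   the profile was sampled on an [extend_path()]-padded coordinate, not
#'   reaction features.
#' @return a `stationary_table`: data.frame with `label`, `kind`
#'   ("minimum"/"maximum"), `s`, `free_energy`, `error`. A monotonic profile
#'   yields the endpoints only, with attribute `note`.
#' @export
extract_stationary <- function(profile, smoothing_window = 5,
                               min_prominence = 0.5, labels = NULL,
                               trim_boundary_maxima = FALSE) {
  ok <- which(is.finite(profile$free_energy))
  if (!length(ok)) stop("profile is empty")
  s <- profile$s[ok]
  g <- smooth_profile(profile$free_energy[ok], smoothing_window)
  err <- if ("uncertainty" %in% names(profile)) profile$uncertainty[ok] else
    rep(NA_real_, length(ok))
  n <- length(g)
  dg <- diff(g)
  sgn <- sign(dg)
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  turns <- which(diff(sgn) != 0) + 1L
  idx <- c(1L, turns, n)
  idx <- idx[!duplicated(idx)]
  kind <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    left <- if (j == 1) NA else g[idx[j - 1]]
    right <- if (j == length(idx)) NA else g[idx[j + 1]]
    nb <- c(left, right)
    if (all(is.na(nb))) "minimum"
    else if (g[i] <= min(nb, na.rm = TRUE)) "minimum" else "maximum"
  }, character(1))
  # enforce strict alternation by keeping the more extreme of same-kind runs
  # (a boundary entry competing with a deeper interior basin loses)
  dedupe <- function(idx, kind) {
    j <- 1L
    while (j < length(idx)) {
      if (kind[j] == kind[j + 1]) {
        better <- if (kind[j] == "minimum") g[idx[j + 1]] < g[idx[j]]
        else g[idx[j + 1]] > g[idx[j]]
        drop <- if (better) j else j + 1L
        idx <- idx[-drop]; kind <- kind[-drop]
        j <- max(1L, j - 1L)
      } else j <- j + 1L
    }
    list(idx = idx, kind = kind)
  }
  d <- dedupe(idx, kind)
  idx <- d$idx; kind <- d$kind
  # prune low-prominence adjacent pairs (never removing the endpoints)
  repeat {
    if (length(idx) <= 2) break
    amp <- abs(diff(g[idx]))
    weak <- which(amp < min_prominence)
    if (!length(weak)) break
    j <- weak[which.min(amp[weak])]      # pair (j, j+1)
    interior <- setdiff(c(j, j + 1L), c(1L, length(idx)))
    idx <- idx[-interior]; kind <- kind[-interior]
    d <- dedupe(idx, kind)
    idx <- d$idx; kind <- d$kind
  }
  if (trim_boundary_maxima) {
    if (length(idx) > 1 && kind[1] == "maximum" && idx[1] == 1L) {
      idx <- idx[-1]; kind <- kind[-1]
    }
    last <- length(idx)
    if (last > 1 && kind[last] == "maximum" && idx[last] == n) {
      idx <- idx[-last]; kind <- kind[-last]
    }
  }
  note <- NULL
  if (all(idx %in% c(1L, n))) {
    note <- "no interior extremum; endpoints only"
  }
  if (is.null(labels)) {
    nm <- cumsum(kind == "minimum"); nt <- cumsum(kind == "maximum")
    labels <- ifelse(kind == "minimum", paste0("M", nm), paste0("TS", nt))
  } else if (length(labels) != length(idx)) {
    stop(sprintf("%d labels supplied for %d stationary points",
                 length(labels), length(idx)))
  }
  out <- data.frame(label = labels, kind = kind, s = s[idx],
                    free_energy = g[idx], error = err[idx],
                    stringsAsFactors = FALSE)
  attr(out, "note") <- note
  class(out) <- c("stationary_table", "data.frame")
  out
}
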