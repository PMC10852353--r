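#' Initialise an adaptive string
#'
#' Places `n_nodes` replicas on the straight segment between the two endpoint
#' configurations, equidistant in the mass-weighted metric (for a straight
#' segment this coincides with uniform parameter spacing).
#'
#' @param endpoint_a,endpoint_b distinct CV vectors (reactant / product).
#' @param n_nodes number of nodes (>= 3; 32 by default, chosen so node spacing
#'   stays well below basin widths on the calibrated landscapes).
#' @param metric_masses per-CV masses (amu) of the mass-weighted metric;
#'   transferred-proton CVs conventionally carry 2 amu.
#' @param node_stiffness harmonic restraint stiffness holding each walker at
#'   its node (kcal/mol/A^2).
#' @return a `string_state` with fields `nodes` (N x D), `node_stiffness`,
#'   `metric_masses`, `iteration`, `rmsd_history`, `converged`.
#' @export
initialize_string <- function(endpoint_a, endpoint_b, n_nodes = 32,
                              metric_masses = rep(1, length(endpoint_a)),
                              node_stiffness = 200) {
  a <- as.numeric(endpoint_a); b <- as.numeric(endpoint_b)
  if (length(a) != length(b)) stop("endpoint dimension mismatch")
  if (sqrt(sum((a - b)^2)) < 1e-12) stop("endpoints must be distinct")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  frac <- seq(0, 1, length.out = n_nodes)
  nodes <- outer(rep(1, n_nodes), a) + outer(frac, b - a)
  structure(list(nodes = nodes, node_stiffness = node_stiffness,
                 metric_masses = rep(metric_masses, length.out = length(a)),
                 iteration = 0L,
                 rmsd_history = data.frame(iteration = integer(),
                                           rmsd = numeric()),
                 converged = FALSE, avg_nodes = nodes,
                 steps_per_iteration = NA_integer_),
            class = "string_state")
}

#' @export
print.string_state <- function(x, ...) {
  cat(sprintf("<string_state> %d nodes x %d CV(s), iteration %d, %s\n",
              nrow(x$nodes), ncol(x$nodes), x$iteration,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  if (nrow(x$rmsd_history)) {
    cat(sprintf("  last RMSD vs running average: %.4g amu^1/2 A\n",
                utils::tail(x$rmsd_history$rmsd, 1)))
  }
  invisible(x)
}

# mass-weighted string RMSD in amu^1/2 * Angstrom
string_rmsd <- function(nodes_a, nodes_b, masses) {
  D <- mass_weight(nodes_a, masses) - mass_weight(nodes_b, masses)
  sqrt(mean(rowSums(D^2)))
}

# Resample nodes to equal mass-weighted arc length along the piecewise-linear
# string; endpoints are conserved exactly. Resampled nodes lie on the original
# polyline, but their chord (node-to-node) distances only approximate the
# along-path spacing when a kink falls between nodes, so the resampling is
# iterated until consecutive chord lengths are equal to 1e-8 relative.
reparametrize_string <- function(nodes, masses) {
  Y0 <- mass_weight(nodes, masses)
  arc0 <- c(0, cumsum(sqrt(rowSums(diff(Y0)^2))))
  n <- nrow(nodes)
  interp <- function(tgt) {
    out <- sapply(seq_len(ncol(Y0)), function(j) {
      stats::approx(arc0, Y0[, j], xout = tgt, ties = "ordered")$y
    })
    matrix(out, n)
  }
  tgt <- seq(0, arc0[length(arc0)], length.out = n)
  for (it in 1:50) {
    Y <- interp(tgt)
    seg <- sqrt(rowSums(diff(Y)^2))
    if (diff(range(seg)) / mean(seg) < 1e-8) break
    # remap: equal spacing in the chord-length parametrisation of the
    # current points, pulled back to the original polyline parameter
    chord <- c(0, cumsum(seg))
    tgt <- stats::approx(chord, tgt,
                         xout = seq(0, chord[n], length.out = n),
                         ties = "ordered")$y
  }
  sweep(Y, 2, sqrt(rep(masses, length.out = ncol(nodes))), "/")
}

#' Metropolis Hamiltonian exchange between neighbour nodes
#'
#' Attempts configuration swaps between neighbouring string nodes with
#' acceptance min(1, exp(-beta * Delta)),
#' Delta = U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j), where U_k is the node-k
#' biased Hamiltonian. Since all nodes share the same underlying potential,
#' only the restraint energies enter Delta. Pairing alternates between
#' even-start (1-2, 3-4, ...) and odd-start (2-3, 4-5, ...) across calls,
#' driven by `parity`.
#'
#' @param positions N x D matrix of current walker configurations (row k is
#'   the walker of node k).
#' @param centers N x D matrix of restraint centers (the nodes).
#' @param stiffness restraint stiffness (scalar).
#' @param temperature temperature (K).
#' @param parity `"even"` pairs (1,2),(3,4),...; `"odd"` pairs (2,3),(4,5),...
#' @param velocities optional N x D matrix swapped alongside positions.
#' @return list with permuted `positions` (and `velocities`), logical
#'   `accepted` per attempted pair, and the `delta` values.
#' @export
attempt_neighbor_exchange <- function(positions, centers, stiffness,
                                      temperature = 310,
                                      parity = c("even", "odd"),
                                      velocities = NULL) {
  parity <- match.arg(parity)
  N <- nrow(positions)
  i <- seq(if (parity == "even") 1L else 2L, N - 1L, by = 2L)
  j <- i + 1L
  bias <- function(rows_x, rows_c) {
    0.5 * stiffness * rowSums((positions[rows_x, , drop = FALSE] -
                                 centers[rows_c, , drop = FALSE])^2)
  }
  delta <- (bias(j, i) + bias(i, j)) - (bias(i, i) + bias(j, j))
  accepted <- is.finite(delta) &
    stats::runif(length(i)) < exp(-delta / kBT(temperature))
  ai <- i[accepted]; aj <- j[accepted]
  if (length(ai)) {
    tmp <- positions[ai, , drop = FALSE]
    positions[ai, ] <- positions[aj, , drop = FALSE]
    positions[aj, ] <- tmp
    if (!is.null(velocities)) {
      tmp <- velocities[ai, , drop = FALSE]
      velocities[ai, ] <- velocities[aj, , drop = FALSE]
      velocities[aj, ] <- tmp
    }
  }
  list(positions = positions, velocities = velocities, accepted = accepted,
       delta = delta)
}

#' One adaptive-string iteration
#'
#' Samples every node under its harmonic restraint (all nodes stepped in
#' lockstep by the Langevin engine, with Hamiltonian neighbour exchange every
#' `exchange_every` steps), estimates the free-energy gradient at each node
#' from the mean restraint displacement, g = -k (<x> - center), moves interior
#' nodes along the negative gradient component transverse to the local path
#' tangent (in the mass-weighted metric), relaxes the endpoints by full
#' steepest descent within their basins, and reparametrises the string to
#' equal mass-weighted arc length. The mass-weighted RMSD of the new string
#' against the running-average string is appended to the history.
#'
#' @param state a `string_state`.
#' @param pot the [potential()] sampled.
#' @param config a [sampler_config()] for the per-node sampling (its seed is
#'   combined with the iteration counter).
#' @param step_size gradient-descent rate (A^2 mol/kcal); displacements are
#'   capped at half the node spacing per iteration.
#' @param exchange_every attempt neighbour exchange every this many steps
#'   (0 disables; default 50).
#' @return the updated `string_state`.
#' @export
string_iteration <- function(state, pot, config, step_size = 0.01,
                             exchange_every = 50L) {
  if (pot$dimension != ncol(state$nodes)) stop("potential dimension mismatch")
  C <- state$nodes
  N <- nrow(C); d <- ncol(C)
  k <- state$node_stiffness
  parity_flip <- 0L
  exch <- function(X, V, step) {
    parity_flip <<- parity_flip + 1L
    sw <- attempt_neighbor_exchange(X, C, k, config$temperature,
                                    parity = if (parity_flip %% 2L)
                                      "even" else "odd",
                                    velocities = V)
    list(X = sw$positions, V = sw$velocities)
  }
  masses <- if (!is.null(config$masses)) config$masses else pot$masses
  res <- with_seed(derive_seed(config$seed, state$iteration + 1L), {
    lengine(function(X) pot$gradient(X) + k * (X - C), C, masses, config,
            observe_fn = function(X) X, record = "mean",
            exchange_fn = if (exchange_every > 0L) exch else NULL,
            exchange_every = as.integer(exchange_every))
  })
  grad <- -k * (res$mean - C)           # free-energy gradient estimate
  if (!all(is.finite(grad))) stop("non-finite free-energy gradient estimate")

  msq <- sqrt(rep(state$metric_masses, length.out = d))
  Y <- sweep(C, 2, msq, "*")
  gY <- sweep(grad, 2, msq, "/")
  move <- -step_size * gY               # endpoints: full steepest descent
  if (N > 2) {
    tang <- Y[3:N, , drop = FALSE] - Y[1:(N - 2), , drop = FALSE]
    tang <- tang / sqrt(rowSums(tang^2))
    gI <- gY[2:(N - 1), , drop = FALSE]
    gPar <- rowSums(gI * tang) * tang
    move[2:(N - 1), ] <- -step_size * (gI - gPar)
  }
  spacing <- mean(sqrt(rowSums(diff(Y)^2)))
  cap <- spacing / 2
  mlen <- sqrt(max(rowSums(move^2)))
  if (mlen > cap) move <- move * (cap / mlen)

  new_nodes <- NULL
  for (try in 0:10) {
    cand <- sweep(Y + move, 2, msq, "/")
    seg <- sqrt(rowSums(diff(mass_weight(cand, state$metric_masses))^2))
    if (all(seg > 1e-9 * spacing)) { new_nodes <- cand; break }
    move <- move / 2
  }
  if (is.null(new_nodes)) stop("node collision persisted after 10 step halvings")
  new_nodes <- reparametrize_string(new_nodes, state$metric_masses)

  rmsd <- string_rmsd(new_nodes, state$avg_nodes, state$metric_masses)
  it <- state$iteration + 1L
  state$avg_nodes <- (state$avg_nodes * state$iteration + new_nodes) / it
  state$nodes <- new_nodes
  state$iteration <- it
  state$rmsd_history <- rbind(state$rmsd_history,
                              data.frame(iteration = it, rmsd = rmsd))
  state$steps_per_iteration <- config$n_steps
  state$timestep <- config$timestep
  state
}

#' String convergence check
#'
#' TRUE iff the mass-weighted RMSD between the string and its running average
#' stayed at or below `threshold` over a trailing window equivalent to
#' `window_steps` sampling steps (default 2000 steps = 2 ps at a 1 fs
#' timestep; the window is converted to iterations through the steps sampled
#' per iteration).
#'
#' @param state a `string_state` with nonempty history.
#' @param window_steps trailing window in sampler steps.
#' @param threshold RMSD threshold (amu^1/2 A; default 0.1).
#' @return logical; FALSE with attribute `note` when the history is shorter
#'   than the window.
#' @export
check_convergence <- function(state, window_steps = 2000, threshold = 0.1) {
  h <- state$rmsd_history
  if (!nrow(h)) stop("rmsd_history is empty")
  spi <- state$steps_per_iteration
  if (is.na(spi)) spi <- window_steps
  w <- max(1L, as.integer(ceiling(window_steps / spi)))
  if (nrow(h) < w) {
    return(structure(FALSE, note = sprintf(
      "history (%d iterations) shorter than the %d-iteration window",
      nrow(h), w)))
  }
  all(utils::tail(h$rmsd, w) <= threshold)
}

#' Run the adaptive string method to convergence
#'
#' Iterates [string_iteration()] until [check_convergence()] succeeds or
#' `max_iter` is reached.
#'
#' @inheritParams string_iteration
#' @param endpoint_a,endpoint_b reactant and product CV vectors (default: the
#'   first and last calibration stations of a landscape built with
#'   [make_reaction_landscape()]).
#' @param n_nodes,node_stiffness,metric_masses see [initialize_string()].
#' @param threshold,window_steps see [check_convergence()].
#' @param max_iter iteration cap.
#' @param min_iter minimum number of iterations before convergence may be
#'   declared.
#' @param verbose print per-iteration RMSD.
#' @return the final `string_state` (with `converged` set).
#' @export
run_string <- function(pot, endpoint_a = NULL, endpoint_b = NULL,
                       n_nodes = 32, node_stiffness = 200,
                       metric_masses = pot$masses, config,
                       step_size = 0.01, exchange_every = 50L,
                       threshold = 0.1, window_steps = 2000,
                       max_iter = 100L, min_iter = 5L, verbose = FALSE) {
  st <- attr(pot, "stations")
  if (is.null(endpoint_a)) {
    if (is.null(st)) stop("endpoints required for a potential without stations")
    endpoint_a <- st[1, ]
  }
  if (is.null(endpoint_b)) endpoint_b <- st[nrow(st), ]
  state <- initialize_string(endpoint_a, endpoint_b, n_nodes,
                             metric_masses = metric_masses,
                             node_stiffness = node_stiffness)
  w <- max(2L, as.integer(ceiling(window_steps / config$n_steps)))
  recent <- list()
  for (it in seq_len(max_iter)) {
    state <- string_iteration(state, pot, config, step_size = step_size,
                              exchange_every = exchange_every)
    recent <- c(recent, list(state$nodes))
    if (length(recent) > w) recent <- recent[-1]
    if (verbose) {
      message(sprintf("string iteration %3d: rmsd %.4f", it,
                      utils::tail(state$rmsd_history$rmsd, 1)))
    }
    if (it >= min_iter &&
        isTRUE(check_convergence(state, window_steps, threshold))) {
      state$converged <- TRUE
      break
    }
  }
  # average over the trailing window to suppress per-iteration sampling noise
  # in the reported path, then restore exact equidistance
  avg <- Reduce(`+`, recent) / length(recent)
  state$nodes <- reparametrize_string(avg, state$metric_masses)
  state
}
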