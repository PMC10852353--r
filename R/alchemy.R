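#' Thermodynamic integration over a lambda schedule
#'
#' Samples dU/dlambda = V_B - V_A under the mixed Hamiltonian
#' V_lambda = (1 - lambda) V_A + lambda V_B at every schedule point, in
#' independent replicas (all lambda points and replicas stepped in lockstep by
#' the Langevin engine), and integrates the per-replica mean derivative with
#' the trapezoidal rule. The reported error combines the standard error of the
#' replica integrals with a quadrature-truncation estimate (trapezoid vs a
#' natural-spline integral of the mean curve).
#'
#' @param pair an `alchemical_pair` (see [make_alchemical_pair()]).
#' @param schedule lambda points in [0, 1]; must cover 0 and 1 and increase
#'   strictly. Default: 11 equidistant points.
#' @param n_steps,burn_in sampling steps per lambda point and replica.
#' @param replicas independent replicas (default 5).
#' @param seed integer seed.
#' @param friction,timestep Langevin parameters.
#' @param label free-text leg label.
#' @return a `lambda_leg`: list with `schedule`, `mean_dudl`, `se_dudl`
#'   (across replicas), `per_replica_dG`, `replicas`, `dG`, `dG_err`,
#'   `quadrature_err`, `temperature`, `label`.
#' @export
ti_estimate <- function(pair, schedule = seq(0, 1, length.out = 11),
                        n_steps = 20000, burn_in = NULL, replicas = 5,
                        seed = 1, friction = 2, timestep = 1, label = "") {
  if (!inherits(pair, "alchemical_pair")) stop("pair must be an alchemical_pair")
  if (schedule[1] != 0 || schedule[length(schedule)] != 1) {
    stop("schedule must cover lambda = 0 and lambda = 1")
  }
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  replicas <- as.integer(replicas)
  if (replicas < 1) stop("replicas must be >= 1")
  L <- length(schedule)
  d <- pair$dimension
  lam <- rep(schedule, times = replicas)      # walker i has lambda lam[i]
  X0 <- matrix(0, L * replicas, d)
  grad_fn <- function(X) {
    (1 - lam) * pair$A$gradient(X) + lam * pair$B$gradient(X)
  }
  cfg <- sampler_config(n_steps, temperature = pair$temperature,
                        friction = friction, timestep = timestep,
                        burn_in = burn_in, seed = derive_seed(seed, 11L))
  res <- with_seed(cfg$seed, {
    lengine(grad_fn, X0, pair$masses, cfg,
            observe_fn = function(X) pair$dudl(X), record = "mean")
  })
  if (!all(is.finite(res$mean))) stop("non-finite dU/dlambda estimate")
  M <- matrix(res$mean, L, replicas)          # mean dU/dl per (lambda, replica)
  dg_rep <- apply(M, 2, function(y) trapz(schedule, y))
  mean_dudl <- rowMeans(M)
  se_dudl <- if (replicas > 1) apply(M, 1, stats::sd) / sqrt(replicas) else
    rep(NA_real_, L)
  dG <- mean(dg_rep)
  se <- if (replicas > 1) stats::sd(dg_rep) / sqrt(replicas) else 0
  sf <- stats::splinefun(schedule, mean_dudl, method = "natural")
  quad_err <- abs(trapz(schedule, mean_dudl) -
                    stats::integrate(sf, 0, 1, rel.tol = 1e-10)$value)
  structure(list(schedule = schedule, mean_dudl = mean_dudl,
                 se_dudl = se_dudl, per_replica_dG = dg_rep,
                 replicas = replicas, dG = dG,
                 dG_err = sqrt(se^2 + quad_err^2), replica_se = se,
                 quadrature_err = quad_err, temperature = pair$temperature,
                 label = label),
            class = "lambda_leg")
}

#' @export
print.lambda_leg <- function(x, ...) {
  cat(sprintf("<lambda_leg> %s: %d lambda points, %d replicas; dG = %.4f +- %.4f kcal/mol\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$schedule), x$replicas, x$dG, x$dG_err))
  invisible(x)
}

#' Write a lambda leg as CSV
#'
#' Columns `lambda, mean_dudl, se`.
#' @param leg a `lambda_leg`.
#' @param file output path.
#' @export
write_lambda_leg <- function(leg, file) {
  utils::write.csv(data.frame(lambda = leg$schedule, mean_dudl = leg$mean_dudl,
                              se = leg$se_dudl),
                   file, row.names = FALSE)
  invisible(file)
}

check_leg_temperatures <- function(a, b) {
  if (abs(a$temperature - b$temperature) > 1e-9) {
    stop("legs were integrated at different temperatures")
  }
  a$temperature
}

#' pKa from a two-leg thermodynamic cycle
#'
#' Relates the deprotonation free energy in an environment (enzyme) to that of
#' the reference compound in water:
#' pKa = pKa_ref + (dG_env - dG_aq) / (RT ln 10). Leg errors propagate in
#' quadrature.
#'
#' @param leg_env,leg_aq `lambda_leg`s of the environment and aqueous
#'   deprotonations (must share a temperature).
#' @param pKa_reference aqueous reference pKa (default 9.1, free threonine).
#' @return a `pka_cycle`: list with `pKa`, `pKa_err`, `ddG`, `ddG_err`,
#'   `pKa_reference`, `temperature` and both legs.
#' @export
pka_from_cycle <- function(leg_env, leg_aq, pKa_reference = 9.1) {
  temperature <- check_leg_temperatures(leg_env, leg_aq)
  rtln10 <- kBT(temperature) * log(10)
  ddG <- leg_env$dG - leg_aq$dG
  ddG_err <- sqrt(leg_env$dG_err^2 + leg_aq$dG_err^2)
  structure(list(pKa = pKa_reference + ddG / rtln10,
                 pKa_err = ddG_err / rtln10,
                 ddG = ddG, ddG_err = ddG_err,
                 pKa_reference = pKa_reference, temperature = temperature,
                 leg_environment = leg_env, leg_aqueous = leg_aq),
            class = "pka_cycle")
}

#' @export
print.pka_cycle <- function(x, ...) {
  cat(sprintf("<pka_cycle> pKa = %.2f +- %.2f (reference %.2f, ddG = %.3f kcal/mol at %g K)\n",
              x$pKa, x$pKa_err, x$pKa_reference, x$ddG, x$temperature))
  invisible(x)
}

#' Free-energy cost of deprotonation at a given pH
#'
#' RT ln 10 * (pKa - pH); negative when pH exceeds the pKa.
#'
#' @param pKa acid dissociation constant (may carry bootstrap error
#'   separately).
#' @param pH solution pH.
#' @param temperature temperature (K).
#' @return penalty in kcal/mol.
#' @export
#' @examples
#' deprotonation_penalty(8.5, 7.5, 310) # 1.418 kcal/mol
deprotonation_penalty <- function(pKa, pH, temperature = 310) {
  kBT(temperature) * log(10) * (pKa - pH)
}

#' Ligand-release free energy from a two-leg cycle
#'
#' Difference of an annihilation leg in the binding site and one in bulk:
#' dG_release = dG_site - dG_bulk, errors in quadrature. A negative value
#' means release into bulk is favourable.
#'
#' @param leg_site,leg_bulk `lambda_leg`s (same temperature).
#' @return a `release_cycle`: list with `dG_release`, `dG_err` and both legs.
#' @export
release_dg <- function(leg_site, leg_bulk) {
  temperature <- check_leg_temperatures(leg_site, leg_bulk)
  structure(list(dG_release = leg_site$dG - leg_bulk$dG,
                 dG_err = sqrt(leg_site$dG_err^2 + leg_bulk$dG_err^2),
                 temperature = temperature,
                 leg_site = leg_site, leg_bulk = leg_bulk),
            class = "release_cycle")
}

#' @export
print.release_cycle <- function(x, ...) {
  cat(sprintf("<release_cycle> dG_release = %.3f +- %.3f kcal/mol\n",
              x$dG_release, x$dG_err))
  invisible(x)
}
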