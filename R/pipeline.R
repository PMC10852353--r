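#' Full string -> path-CV -> umbrella-sampling -> WHAM pipeline
#'
#' Convenience driver chaining [run_string()], [build_path()],
#' [place_windows()], [umbrella_sample()], [wham()], [pmf_error()] and
#' [extract_stationary()] on one potential, with all seeds derived from a
#' single master seed.
#'
#' @param pot the [potential()] (typically a [make_reaction_landscape()]
#'   surface, whose stations supply the default endpoints).
#' @param endpoint_a,endpoint_b reactant/product CV vectors.
#' @param seed master seed.
#' @param temperature temperature (K).
#' @param n_nodes,node_stiffness,string_steps,string_max_iter,step_size
#'   string-stage parameters ([run_string()]).
#' @param n_windows number of umbrella windows; `NULL` (default) chooses
#'   ~5.6 windows per unit metric path length (48 on the 8.6-unit reference
#'   stage). A fixed count independent of path length would make windows on
#'   short paths so stiff that the 1 fs integrator loses stability.
#' @param window_steps,window_burn,pilot_steps umbrella-stage parameters.
#' @param n_bins,wham_tol WHAM parameters.
#' @param n_resamples,n_blocks bootstrap parameters ([pmf_error()]).
#' @param smoothing_window,min_prominence,labels stationary-point extraction
#'   parameters ([extract_stationary()]).
#' @param pad metric length by which the path is extended beyond the terminal
#'   basins before umbrella sampling (see [extend_path()]).
#' @param zero_reference passed to [wham()].
#' @param verbose print stage progress.
#' @return a `pmf_pipeline` list: `string`, `path`, `windows`, `profile`,
#'   `stationary`.
#' @export
pmf_pipeline <- function(pot, endpoint_a = NULL, endpoint_b = NULL, seed = 1,
                         temperature = 310,
                         n_nodes = 32, node_stiffness = 200,
                         string_steps = 500, string_max_iter = 80,
                         step_size = 0.01,
                         n_windows = NULL, window_steps = 155000,
                         window_burn = 5000, pilot_steps = 5000,
                         n_bins = 200, wham_tol = 1e-10,
                         n_resamples = 100, n_blocks = 20,
                         smoothing_window = 5, min_prominence = 0.5,
                         labels = NULL, pad = 0.3,
                         zero_reference = "first_min",
                         verbose = FALSE) {
  cfg <- sampler_config(string_steps, temperature = temperature,
                        seed = derive_seed(seed, 1000L))
  if (verbose) message("refining string ...")
  string <- run_string(pot, endpoint_a, endpoint_b, n_nodes = n_nodes,
                       node_stiffness = node_stiffness, config = cfg,
                       step_size = step_size, max_iter = string_max_iter,
                       verbose = verbose)
  path <- extend_path(build_path(string, override = TRUE), pad)
  if (is.null(n_windows)) {
    n_windows <- max(8L, as.integer(round(48 / 8.6 * path$total_length)))
  }
  if (verbose) message("calibrating umbrella windows ...")
  windows <- place_windows(pot, path, n_windows = n_windows,
                           temperature = temperature,
                           pilot_steps = pilot_steps,
                           seed = derive_seed(seed, 2000L))
  if (verbose) message("umbrella sampling ...")
  windows <- umbrella_sample(pot, path, windows, n_steps = window_steps,
                             burn_in = window_burn,
                             seed = derive_seed(seed, 3000L))
  if (verbose) message("WHAM + bootstrap ...")
  profile <- wham(windows, n_bins = n_bins, tolerance = wham_tol,
                  zero_reference = zero_reference)
  if (pad > 0) {
    # the outermost bins collect the density piled up by the s in [0,1]
    # projection clamp; with a padded path they lie inside the confinement
    # walls and carry no reaction information
    profile$free_energy[c(1L, nrow(profile))] <- NA_real_
  }
  profile <- pmf_error(windows, profile, n_resamples = n_resamples,
                       n_blocks = n_blocks, seed = derive_seed(seed, 4000L))
  stationary <- extract_stationary(profile,
                                   smoothing_window = smoothing_window,
                                   min_prominence = min_prominence,
                                   labels = labels,
                                   trim_boundary_maxima = pad > 0)
  structure(list(string = string, path = path, windows = windows,
                 profile = profile, stationary = stationary, seed = seed),
            class = "pmf_pipeline")
}

#' @export
print.pmf_pipeline <- function(x, ...) {
  cat("<pmf_pipeline>\n")
  print(x$string)
  print(x$profile)
  cat("stationary points:\n")
  print(as.data.frame(x$stationary), digits = 4, row.names = FALSE)
  invisible(x)
}
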