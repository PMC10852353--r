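test_that("string initialisation interpolates equidistantly in the metric", {
  st <- initialize_string(c(0, 0), c(1, 0), 5)
  expect_equal(st$nodes[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(st$nodes[, 2], rep(0, 5))

  # anisotropic masses: equal spacing in the mass-weighted, hence also the
  # Euclidean, parametrisation of a straight segment
  st2 <- initialize_string(c(0, 0), c(1, 2), 7, metric_masses = c(4, 1))
  Y <- sweep(st2$nodes, 2, sqrt(c(4, 1)), "*")
  seg <- sqrt(rowSums(diff(Y)^2))
  expect_lt(diff(range(seg)) / mean(seg), 1e-6)

  expect_equal(st2$nodes[1, ], c(0, 0))
  expect_equal(st2$nodes[7, ], c(1, 2))
  expect_error(initialize_string(c(0, 0), c(0, 0), 5), "distinct")
  expect_error(initialize_string(c(0, 0), c(1, 0), 2), ">= 3")
})

test_that("reparametrisation equalises metric arc lengths and fixes endpoints", {
  set.seed(5)
  nodes <- cbind(sort(stats::runif(9)), stats::rnorm(9, 0, 0.2))
  out <- stringfe:::reparametrize_string(nodes, c(2, 1))
  expect_equal(out[1, ], nodes[1, ])
  expect_equal(out[9, ], nodes[9, ])
  Y <- sweep(out, 2, sqrt(c(2, 1)), "*")
  seg <- sqrt(rowSums(diff(Y)^2))
  expect_lt(diff(range(seg)) / mean(seg), 1e-6)
})

test_that("on a quadratic bowl the string stays a straight segment", {
  bowl <- harmonic_potential(c(3, 3), dimension = 2)
  st <- initialize_string(c(-1, 0.8), c(1, 0.8), 11, node_stiffness = 300)
  cfg <- sampler_config(1500, seed = 2)
  for (i in 1:8) st <- string_iteration(st, bowl, cfg, step_size = 0.02)
  # interior nodes stay on the chord between the (relaxing) endpoints
  a <- st$nodes[1, ]; b <- st$nodes[11, ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  D <- sweep(st$nodes, 2, a)
  transverse <- D - tcrossprod(as.numeric(D %*% u), u)
  expect_lt(max(sqrt(rowSums(transverse^2))), 0.01)
})

test_that("the string converges through the Mueller-Brown saddles", {
  mb <- muller_brown()
  minima <- attr(mb, "minima")
  saddles <- attr(mb, "saddles")
  # the canonical surface is far stiffer than a kcal/Angstrom landscape:
  # finer timestep, stiffer node restraints, tighter convergence
  cfg <- sampler_config(1000, temperature = 1500, timestep = 0.1, seed = 8)
  st <- run_string(mb, minima[3, ], minima[1, ], n_nodes = 25,
                   node_stiffness = 4000, config = cfg, step_size = 3e-4,
                   threshold = 0.05, max_iter = 200, min_iter = 40,
                   window_steps = 4000)
  path <- build_path(st, override = TRUE)
  walk <- path_point(path, seq(0, 1, length.out = 2000))
  for (k in 1:2) {
    dmin <- min(sqrt(rowSums(sweep(walk, 2, saddles[k, ])^2)))
    expect_lt(dmin, 0.05)
  }
})

test_that("converged endpoints stay at the terminal minima", {
  spec <- asnase3_regeneration_spec()
  L <- make_reaction_landscape(spec)
  stations <- attr(L, "stations")
  cfg <- sampler_config(500, seed = 4)
  st <- run_string(L, config = cfg, n_nodes = 16, max_iter = 40)
  expect_equal(nrow(st$nodes), 16)
  # endpoint relaxation is stochastic: the averaged endpoints must sit within
  # the mean-force noise floor of the true terminal minima
  expect_lt(sqrt(sum((st$nodes[1, ] - stations[1, ])^2)), 0.05)
  expect_lt(sqrt(sum((st$nodes[16, ] - stations[3, ])^2)), 0.05)
})

test_that("neighbour exchange accepts degenerate swaps and alternates parity", {
  pos <- matrix(rep(c(0.5, 0.5), 4), 4, 2, byrow = TRUE)
  cen <- pos
  set.seed(1)
  sw <- attempt_neighbor_exchange(pos, cen, 100, parity = "even")
  expect_true(all(sw$accepted))
  expect_equal(sw$delta, rep(0, 2))
  sw2 <- attempt_neighbor_exchange(pos, cen, 100, parity = "odd")
  expect_equal(length(sw2$accepted), 1L)
})

test_that("exchange is attempted exactly every 50 steps by default", {
  calls <- 0L
  cfg <- sampler_config(500, seed = 9, burn_in = 0)
  grad_fn <- function(X) X
  with_seed <- stringfe:::with_seed
  with_seed(1, {
    stringfe:::lengine(grad_fn, matrix(0, 4, 1), 1, cfg,
                       observe_fn = function(X) X[, 1], record = "mean",
                       exchange_fn = function(X, V, step) {
                         calls <<- calls + 1L
                         expect_equal(step %% 50L, 0L)
                         list(X = X, V = V)
                       },
                       exchange_every = 50L)
  })
  expect_equal(calls, 10L)
})

test_that("exchange preserves each node's Boltzmann marginal (detailed balance)", {
  hp <- harmonic_potential(1)
  k <- 30
  centers <- matrix(c(-0.4, 0.4), 2, 1)
  grad_fn <- function(X) hp$gradient(X) + k * (X - centers)
  cfg <- sampler_config(60000, seed = 77, burn_in = 5000)
  res <- stringfe:::with_seed(cfg$seed, {
    stringfe:::lengine(grad_fn, centers, 1, cfg,
                       observe_fn = function(X) X[, 1], record = "series",
                       exchange_fn = function(X, V, step) {
                         sw <- attempt_neighbor_exchange(X, centers, k,
                                                         310, "even", V)
                         list(X = sw$positions, V = sw$velocities)
                       },
                       exchange_every = 50L)
  })
  for (i in 1:2) {
    restr <- harmonic_restraint(centers[i, ], k)
    mu_ref <- equilibrium_moment(hp, function(X) X[, 1],
                                 box = matrix(c(-3, 3), 1),
                                 restraint = restr, n_grid = 1501)
    se <- batch_se(res$series[, i])
    expect_lt(abs(mean(res$series[, i]) - mu_ref), 3 * max(se, 2e-3))
  }
})

test_that("convergence criterion reads the trailing RMSD window", {
  st <- initialize_string(c(0, 0), c(1, 0), 5)
  st$steps_per_iteration <- 500L
  # identical consecutive strings: rmsd 0 -> converged
  st$rmsd_history <- data.frame(iteration = 1:4, rmsd = rep(0, 4))
  expect_true(check_convergence(st, window_steps = 2000, threshold = 0.1))
  # rmsd stuck at 0.2 with threshold 0.1 -> not converged
  st$rmsd_history$rmsd <- rep(0.2, 4)
  expect_false(check_convergence(st, window_steps = 2000, threshold = 0.1))
  # crossing below threshold for exactly the window -> converged only then
  st$rmsd_history <- data.frame(iteration = 1:10,
                                rmsd = c(rep(0.5, 6), rep(0.09, 4)))
  expect_true(check_convergence(st, window_steps = 2000, threshold = 0.1))
  st$rmsd_history$rmsd[7] <- 0.3
  expect_false(check_convergence(st, window_steps = 2000, threshold = 0.1))
  # history shorter than the window
  st$rmsd_history <- data.frame(iteration = 1, rmsd = 0)
  out <- check_convergence(st, window_steps = 2000, threshold = 0.1)
  expect_false(out)
  expect_match(attr(out, "note"), "shorter")
})
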