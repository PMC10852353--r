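flat_potential_2d <- function() {
  potential(function(X) rep(0, nrow(X)),
            function(X) X * 0, 2, label = "flat",
            box = rbind(c(-1, 2), c(-1, 1)))
}

test_that("windows are placed with interior centers and the 4kT/ds^2 stiffness", {
  p <- build_path(rbind(c(0, 0), c(1, 0)))
  w <- place_windows(flat_potential_2d(), p, n_windows = 2,
                     pilot_steps = 2000, seed = 1)
  expect_equal(w$centers, c(0.25, 0.75))
  expect_equal(w$initial_stiffness,
               rep(4 * kBT(310) / 0.5^2, 2))
  expect_error(place_windows(flat_potential_2d(), p, n_windows = 1), ">= 2")
})

test_that("on a flat profile the on-the-fly rescaling stays near unity", {
  p <- build_path(rbind(c(0, 0), c(1, 0)))
  # high friction decorrelates the pilot's variance estimate; at the default
  # underdamped 2 ps^-1 the sd of a window's sd estimate would dominate
  w <- place_windows(flat_potential_2d(), p, n_windows = 8,
                     pilot_steps = 20000, seed = 2, friction = 20)
  fac <- w$stiffness / w$initial_stiffness
  # the two boundary windows see the s in [0,1] clamp, which truncates their
  # distributions; the flat-profile prediction applies to interior windows
  expect_true(all(fac[2:7] > 0.8 & fac[2:7] < 1.25))
})

test_that("stiff regions reduce the force constant by the squared sd ratio", {
  # extra longitudinal curvature narrows the biased distribution, so the
  # observed sd undershoots the target and the stiffness is scaled down
  stiff <- harmonic_potential(c(400, 50), center = c(0.5, 0), dimension = 2)
  p <- build_path(rbind(c(0, 0), c(1, 0)))
  w <- place_windows(stiff, p, n_windows = 8, pilot_steps = 8000, seed = 3)
  target <- (1 / 8) / 2
  mid <- 4:5
  expect_true(all(w$stiffness[mid] < w$initial_stiffness[mid]))
  expect_equal(w$stiffness[mid],
               w$initial_stiffness[mid] *
                 pmax(0.25, (w$pilot_sd[mid] / target)^2),
               tolerance = 1e-12)
})

test_that("degenerate single-window WHAM reproduces the unbiased histogram", {
  dw <- double_well_potential(barrier = 3)
  grid <- seq(-2, 2, length.out = 4001)
  prob <- exp(-dw$energy(matrix(grid)) / kBT(310))
  set.seed(9)
  x <- sample(grid, 2e5, replace = TRUE, prob = prob)
  s <- (x + 2) / 4   # map onto [0, 1]
  w <- structure(list(centers = 0.5, stiffness = 0, samples = list(s),
                      temperature = 310, range = c(0, 1)),
                 class = "window_set")
  pr <- wham(w, n_bins = 80, zero_reference = "global_min")
  xs <- pr$s * 4 - 2
  ref <- dw$energy(matrix(xs))
  ref <- ref - min(ref[is.finite(pr$free_energy)])
  keep <- is.finite(pr$free_energy) & ref < 2.5
  expect_lt(max(abs(pr$free_energy[keep] - ref[keep])), 0.1)
})

test_that("8-window WHAM on a harmonic well matches the quadrature profile", {
  pot <- harmonic_potential(2)
  p <- build_path(matrix(c(-1.9, 1.9), 2, 1))
  w <- place_windows(pot, p, n_windows = 8, pilot_steps = 6000, seed = 30,
                     friction = 20)
  w <- umbrella_sample(pot, p, w, n_steps = 102000, burn_in = 2000,
                       seed = 40, friction = 20)
  pr <- wham(w, n_bins = 120, zero_reference = "global_min")
  xs <- pr$s * 3.8 - 1.9
  ref <- pot$energy(matrix(xs))
  ref <- ref - min(ref)
  keep <- is.finite(pr$free_energy) & ref < 6 & abs(xs) < 1.5
  dev <- pr$free_energy[keep] - ref[keep]
  dev <- dev - mean(dev)             # common offset is not part of the PMF
  expect_lt(max(abs(dev)), 0.05)
})

test_that("multi-window WHAM matches the Boltzmann quadrature oracle", {
  tilted <- potential(function(X) 3 * ((X[, 1])^2 - 1)^2 + 0.8 * X[, 1],
                      function(X) cbind(12 * X[, 1] * (X[, 1]^2 - 1) + 0.8),
                      1, label = "tilted double well",
                      box = matrix(c(-1.8, 1.8), 1))
  fixtures <- list(double_well_potential(3), tilted)
  for (k in seq_along(fixtures)) {
    pot <- fixtures[[k]]
    # the path spans wider than the compared region: projection clamps s at
    # the path ends, so the outermost bins collect pile-up density; high
    # friction decorrelates the well-to-well weights
    p <- build_path(matrix(c(-1.9, 1.9), 2, 1))
    w <- place_windows(pot, p, n_windows = 14, pilot_steps = 6000,
                       seed = 30 + k, friction = 20)
    w <- umbrella_sample(pot, p, w, n_steps = 202000, burn_in = 2000,
                         seed = 40 + k, friction = 20)
    pr <- wham(w, n_bins = 120, zero_reference = "global_min")
    xs <- pr$s * 3.8 - 1.9
    ref <- pot$energy(matrix(xs))    # 1-D: the PMF is the potential itself
    ref <- ref - min(ref)
    keep <- is.finite(pr$free_energy) & ref < 6 & abs(xs) < 1.5
    dev <- pr$free_energy[keep] - ref[keep]
    dev <- dev - mean(dev)           # common offset is not part of the PMF
    expect_lt(max(abs(dev)), 0.1)
  }
})

test_that("WHAM errors name non-overlapping windows", {
  w <- structure(list(centers = c(0.2, 0.8),
                      stiffness = c(5000, 5000),
                      samples = list(stats::rnorm(1000, 0.2, 0.01),
                                     stats::rnorm(1000, 0.8, 0.01)),
                      temperature = 310, range = c(0, 1)),
                 class = "window_set")
  expect_error(wham(w, n_bins = 100), "overlap between windows 1")
  expect_error(wham(structure(list(centers = 0.5, samples = NULL),
                              class = "window_set")), "no samples")
})

test_that("stationary extraction locates analytic extrema to the bin", {
  s <- seq(0.0025, 0.9975, by = 0.005)
  g <- 3 + 2 * cos(4 * pi * s)      # extrema at s = 0, .25, .5, .75, 1
  pr <- data.frame(s = s, free_energy = g, uncertainty = 0.01)
  tb <- extract_stationary(pr, smoothing_window = 1, min_prominence = 0.5)
  expect_equal(tb$kind, c("maximum", "minimum", "maximum", "minimum",
                          "maximum"))
  expect_lt(max(abs(tb$s - c(0.0025, 0.25, 0.5, 0.75, 0.9975))), 0.005)
  expect_lt(max(abs(tb$free_energy - (3 + 2 * cos(4 * pi * tb$s)))), 1e-6)

  # monotonic profile: endpoints only, with a note
  mono <- data.frame(s = s, free_energy = 5 * s, uncertainty = 0)
  tb2 <- extract_stationary(mono, smoothing_window = 1)
  expect_equal(nrow(tb2), 2L)
  expect_match(attr(tb2, "note"), "endpoints only")

  # low-prominence wiggles are pruned
  wig <- data.frame(s = s, free_energy = 5 * s + 0.1 * sin(20 * pi * s),
                    uncertainty = 0)
  tb3 <- extract_stationary(wig, smoothing_window = 1, min_prominence = 0.5)
  expect_equal(nrow(tb3), 2L)

  expect_error(extract_stationary(pr, smoothing_window = 1,
                                  labels = c("a", "b")), "labels")
})

test_that("bootstrap uncertainties are seeded and shrink with sampling", {
  pot <- double_well_potential(2)
  p <- build_path(matrix(c(-1.5, 1.5), 2, 1))
  w0 <- place_windows(pot, p, n_windows = 10, pilot_steps = 4000, seed = 51)
  get_err <- function(n_steps, seed) {
    w <- umbrella_sample(pot, p, w0, n_steps = n_steps, burn_in = 2000,
                         seed = seed)
    pr <- wham(w, n_bins = 100, zero_reference = "global_min")
    pmf_error(w, pr, n_resamples = 40, n_blocks = 10, seed = 7)
  }
  pr1 <- get_err(12000, 61)
  pr1b <- get_err(12000, 61)
  expect_identical(pr1$uncertainty, pr1b$uncertainty)
  # same seed: the longer run extends the shorter one, isolating the
  # sample-size effect from run-to-run spread of the uncertainty estimate
  pr2 <- get_err(22000, 61)
  mid <- pr1$s > 0.15 & pr1$s < 0.85   # edge bins are pile-up dominated
  ratio <- mean(pr2$uncertainty[mid], na.rm = TRUE) /
    mean(pr1$uncertainty[mid], na.rm = TRUE)
  # doubling the samples should shrink errors roughly like 1/sqrt(n)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.85)
  expect_error(pmf_error(w0, pr1, n_resamples = 1), ">= 2")
})
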