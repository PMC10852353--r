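# Shared fixtures and independent oracles used across the suite.

# Exact PMF along a calibrated landscape's curve by transverse Gaussian
# quadrature at the stations (independent of the sampling machinery).
station_pmf_quadrature <- function(landscape, temperature = 310,
                                   z_half = 1.5, n_z = 2001) {
  st <- attr(landscape, "stations")
  beta <- 1 / kBT(temperature)
  z <- seq(-z_half, z_half, length.out = n_z)
  vapply(seq_len(nrow(st)), function(i) {
    X <- cbind(st[i, 1], st[i, 2] + z)
    -log(sum(exp(-beta * landscape$energy(X)))) / beta
  }, numeric(1))
}

# Brute-force nearest-point projection onto a path by dense discretisation.
brute_project <- function(x, path, n_per_seg = 4000) {
  msq <- sqrt(rep(path$metric_masses, length.out = ncol(path$nodes)))
  y <- as.numeric(x) * msq
  best <- c(s = NA, z = Inf)
  nseg <- nrow(path$nodes) - 1
  for (j in seq_len(nseg)) {
    tt <- seq(0, 1, length.out = n_per_seg)
    P <- path$nodes[j, ] %o% rep(1, n_per_seg) +
      (path$nodes[j + 1, ] - path$nodes[j, ]) %o% tt
    Pm <- P * msq
    d <- sqrt(colSums((Pm - y)^2))
    k <- which.min(d)
    if (d[k] < best["z"]) {
      seglen <- path$arc_lengths[j + 1] - path$arc_lengths[j]
      best <- c(s = (path$arc_lengths[j] + tt[k] * seglen) / path$total_length,
                z = d[k])
    }
  }
  best
}

# Batch-means standard error of the mean of a correlated series.
batch_se <- function(x, n_batch = 20) {
  b <- split(x, cut(seq_along(x), n_batch, labels = FALSE))
  m <- vapply(b, mean, numeric(1))
  stats::sd(m) / sqrt(n_batch)
}

# Random alternating free-energy cycle for barrier-oracle equivalence tests.
random_cycle <- function(n_ts, seed) {
  set.seed(seed)
  n <- 2 * n_ts + 1
  kind <- rep(c("minimum", "maximum"), length.out = n)
  g <- numeric(n)
  g[1] <- round(stats::runif(1, -3, 3), 3)
  for (i in 2:n) {
    g[i] <- if (kind[i] == "maximum") {
      max(g[i - 1], if (i < n) -Inf else -Inf) + stats::runif(1, 0.5, 12)
    } else g[i - 1] - stats::runif(1, 0.5, 15)
  }
  # ensure each maximum also exceeds its right minimum by construction order:
  # maxima are set above the left minimum; right minimum is drawn below it.
  tb <- data.frame(label = paste0("S", seq_len(n)), kind = kind,
                   free_energy = g, stringsAsFactors = FALSE)
  cand <- which(kind == "minimum")[-1]
  n_marks <- min(sample(0:2, 1), length(cand))
  marks <- sort(cand[sample.int(length(cand), n_marks)])
  list(table = tb, mark_labels = tb$label[marks])
}

# Exhaustive-enumeration effective barrier: all (minimum i, maximum j > i)
# pairs with no irreversible mark position p satisfying i <= p < j.
brute_effective_barrier <- function(states, mark_positions) {
  best <- -Inf; who <- NULL
  for (j in which(states$kind == "maximum")) {
    for (i in which(states$kind == "minimum")) {
      if (i >= j) next
      if (any(mark_positions >= i & mark_positions < j)) next
      b <- states$G[j] - states$G[i]
      if (b > best) { best <- b; who <- c(i, j) }
    }
  }
  list(barrier = best, resting = states$state[who[1]], ts = states$state[who[2]])
}
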