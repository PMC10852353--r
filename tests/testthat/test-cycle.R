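acyl_stage <- function() {
  stage_profile(as.data.frame(asnase3_acylation_spec()),
                stage_label = "acylation", reference = "Michaelis")
}
deacyl_stage <- function() {
  stage_profile(as.data.frame(asnase3_hydrolysis_spec()),
                stage_label = "deacylation", reference = "ACE")
}
regen_stage <- function() {
  stage_profile(as.data.frame(asnase3_regeneration_spec()),
                stage_label = "regeneration", reference = "P")
}
release_corr <- function() {
  list(after_state = "ACE+NH3", label = "ammonia release", value = -4.47,
       error = 0.04)
}

test_that("the acylation stage plus ammonia release nets about -1.8", {
  cyc <- join_stages(list(acyl_stage(), deacyl_stage()),
                     corrections = list(release_corr()))
  ace <- cyc$states$G[cyc$states$state == "ACE"]
  expect_equal(ace, 2.7 - 4.47, tolerance = 1e-12)
  expect_lt(abs(ace - (-1.8)), 0.05)
})

test_that("a single stage with no corrections assembles to itself", {
  cyc <- join_stages(list(deacyl_stage()))
  expect_equal(cyc$states$G, asnase3_hydrolysis_spec()$free_energy)
  expect_equal(cyc$states$state, asnase3_hydrolysis_spec()$label)
})

test_that("continuity and conservation hold on randomised 3-stage toys", {
  for (r in 1:25) {
    set.seed(r)
    stages <- lapply(1:3, function(k) {
      n <- 2 * sample(1:3, 1) + 1
      kind <- rep(c("minimum", "maximum"), length.out = n)
      g <- numeric(n); g[1] <- 0
      for (i in 2:n) {
        g[i] <- if (kind[i] == "maximum") g[i - 1] + stats::runif(1, 1, 10)
        else g[i - 1] - stats::runif(1, 1, 12)
      }
      stage_profile(data.frame(label = sprintf("s%d_%d", k, seq_len(n)),
                               kind = kind, free_energy = g),
                    stage_label = paste0("stage", k), reference = "r")
    })
    junctions <- c(utils::tail(stages[[1]]$table$label, 1),
                   utils::tail(stages[[2]]$table$label, 1))
    corr <- list(list(after_state = junctions[1], label = "c1",
                      value = round(stats::rnorm(1), 3)),
                 list(after_state = junctions[2], label = "c2",
                      value = round(stats::rnorm(1), 3)))
    cyc <- join_stages(stages, corrections = corr)
    st <- cyc$states
    # continuity: each stage's reactant equals the corrected previous product
    for (k in 2:3) {
      first_k <- which(st$stage == paste0("stage", k))[1]
      expect_equal(st$G[first_k],
                   st$G[first_k - 1] + corr[[k - 1]]$value,
                   tolerance = 1e-12)
    }
    # conservation: final state equals the independent telescoped sum
    expected_final <- sum(vapply(stages, function(s) {
      utils::tail(s$table$free_energy, 1) - s$table$free_energy[1]
    }, numeric(1))) + corr[[1]]$value + corr[[2]]$value
    expect_equal(utils::tail(st$G, 1), expected_final, tolerance = 1e-12)
  }
})

test_that("assembly rejects dangling references and double-counted penalties", {
  expect_error(join_stages(list(acyl_stage()),
                           corrections = list(list(after_state = "nope",
                                                   label = "x", value = 1))),
               "unknown state")
  expect_error(join_stages(list(acyl_stage(), acyl_stage())), "unique")
  expect_error(join_stages(list(acyl_stage()),
                           corrections = list(list(after_state = "R",
                                                   label = "deprotonation",
                                                   value = 1.4)),
                           deprotonation = "preapplied"),
               "double counting|preapplied AND")
  expect_error(join_stages(list(acyl_stage()), deprotonation = "correction"),
               "no deprotonation")
  expect_error(join_stages(list(acyl_stage()),
                           irreversible_after = "missing"),
               "unknown state")
})

test_that("the full assembled cycle yields the 20.9 barrier from the acyl-enzyme", {
  cyc <- join_stages(list(acyl_stage(), deacyl_stage(), regen_stage()),
                     corrections = list(release_corr()),
                     irreversible_after = "ACE+NH3")
  rep <- effective_barrier(cyc)
  expect_equal(rep$barrier, 20.9, tolerance = 1e-12)
  expect_equal(rep$determining_step, "TS6")
  expect_equal(rep$resting_state, "ACE")
  # overall reaction free energy relative to Michaelis
  expect_equal(utils::tail(cyc$states$G, 1), -7.2, tolerance = 1e-12)
})

test_that("irreversible marks reset the accessible resting-state window", {
  tb <- data.frame(label = c("A", "TSa", "B", "TSb", "C"),
                   kind = c("minimum", "maximum", "minimum", "maximum",
                            "minimum"),
                   free_energy = c(0, 5, -3, 4, -6))
  open <- join_stages(list(stage_profile(tb, "s", "A")))
  expect_equal(effective_barrier(open)$barrier, 4 - (-3))
  gated <- join_stages(list(stage_profile(tb, "s", "A")),
                       irreversible_after = "B")
  rep <- effective_barrier(gated)
  expect_equal(rep$barrier, 5)
  expect_equal(rep$resting_state, "A")
})

test_that("single-barrier profiles reduce to TS minus reactant", {
  tb <- data.frame(label = c("A", "TS", "B"),
                   kind = c("minimum", "maximum", "minimum"),
                   free_energy = c(0, 7.3, -2))
  cyc <- join_stages(list(stage_profile(tb, "only", "A")))
  rep <- effective_barrier(cyc)
  expect_equal(rep$barrier, 7.3)
  expect_error(effective_barrier(join_stages(list(stage_profile(
    data.frame(label = "A", kind = "minimum", free_energy = 0),
    "flat", "A")))), "no transition state")
})

test_that("effective barrier equals exhaustive enumeration on 1000 random cycles", {
  for (r in 1:1000) {
    rc <- random_cycle(n_ts = sample(1:5, 1), seed = r)
    cyc <- join_stages(list(stage_profile(rc$table, "x", "r")),
                       irreversible_after = rc$mark_labels)
    ref <- brute_effective_barrier(cyc$states, cyc$irreversible)
    if (!is.finite(ref$barrier)) {
      expect_error(effective_barrier(cyc), "no admissible")
    } else {
      got <- effective_barrier(cyc)
      expect_identical(got$barrier, ref$barrier)
    }
  }
})

test_that("raising any transition state never decreases the effective barrier", {
  for (r in 1:40) {
    rc <- random_cycle(n_ts = 4, seed = 5000 + r)
    base <- join_stages(list(stage_profile(rc$table, "x", "r")),
                        irreversible_after = rc$mark_labels)
    b0 <- effective_barrier(base)$barrier
    ts_rows <- which(rc$table$kind == "maximum")
    lift <- rc$table
    j <- sample(ts_rows, 1)
    lift$free_energy[j] <- lift$free_energy[j] + stats::runif(1, 0, 5)
    b1 <- effective_barrier(join_stages(list(stage_profile(lift, "x", "r")),
                                        irreversible_after = rc$mark_labels))$barrier
    expect_gte(b1 + 1e-12, b0)
  }
})

test_that("the rendered cycle table matches the printed stage tables", {
  # deprotonation supplied as an explicit correction: the reactant row is the
  # Michaelis complex at 0.0 and subsequent states recover the printed values
  acyl_shift <- as.data.frame(asnase3_acylation_spec())
  acyl_shift$free_energy <- acyl_shift$free_energy - 1.4
  cyc <- join_stages(list(stage_profile(acyl_shift, "acylation", "R"),
                          deacyl_stage()),
                     corrections = list(list(after_state = "R",
                                             label = "deprotonation penalty",
                                             value = 1.4),
                                        release_corr()),
                     deprotonation = "correction")
  tb <- render_cycle_table(cyc)
  expect_equal(nrow(tb), 14L)
  expect_equal(tb$G[tb$state == "R"], 0.0)
  printed <- c(asnase3_acylation_spec()$free_energy,
               asnase3_hydrolysis_spec()$free_energy + 2.7 - 4.47)
  expect_equal(tb$G[-1], printed[-1], tolerance = 1e-12)
  # telescoping: step free energies sum to the overall change
  expect_equal(sum(tb$step_dG[-1]), utils::tail(tb$G, 1) - tb$G[1],
               tolerance = 1e-12)
})

test_that("cycle tables round-trip through CSV bit-exactly", {
  cyc <- join_stages(list(acyl_stage(), deacyl_stage()),
                     corrections = list(release_corr()))
  f <- tempfile(fileext = ".csv")
  write_cycle_csv(cyc, f)
  back <- read_cycle_csv(f)
  ref <- render_cycle_table(cyc)
  expect_identical(back$G, ref$G)
  expect_identical(back$step_dG, ref$step_dG)
  expect_identical(back$state, ref$state)
})
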