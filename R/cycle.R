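#' Stage profile of a catalytic cycle
#'
#' Wraps a stationary table (from [extract_stationary()] or built by hand)
#' as one stage of a catalytic cycle. The first and last entries are the
#' stage's reactant and product and must be minima. Free energies are relative
#' to the stage's own zero-reference state named in `reference`.
#'
#' @param table a `stationary_table` or data.frame with columns `label`,
#'   `kind` ("minimum"/"maximum"/"saddle"), `free_energy` and optionally
#'   `error`.
#' @param stage_label e.g. "acylation", "deacylation", "regeneration".
#' @param reference label of the state the stage energies are referenced to.
#' @return a `stage_profile`.
#' @export
stage_profile <- function(table, stage_label, reference) {
  table <- as.data.frame(table)
  need <- c("label", "kind", "free_energy")
  if (!all(need %in% names(table))) {
    stop("table needs columns label, kind, free_energy")
  }
  if (!"error" %in% names(table)) table$error <- 0
  table$error[is.na(table$error)] <- 0
  table$kind <- ifelse(table$kind == "saddle", "maximum", table$kind)
  if (!all(table$kind %in% c("minimum", "maximum"))) {
    stop("kind must be minimum or maximum/saddle")
  }
  n <- nrow(table)
  if (table$kind[1] != "minimum" || table$kind[n] != "minimum") {
    stop("a stage must start and end at minima (reactant and product)")
  }
  structure(list(table = table, stage_label = stage_label,
                 reference = reference),
            class = "stage_profile")
}

#' Join stage profiles into an assembled catalytic cycle
#'
#' Concatenates the stages in order, offsetting each so that its reactant
#' free energy equals the previous stage's (corrected) product free energy,
#' and applying scalar corrections (e.g. a ligand-release free energy after
#' the state where the ligand departs, or a nucleophile-deprotonation penalty
#' at the start). Absolute energies are referenced to the first stage's
#' reference state (Michaelis analog) at 0.
#'
#' @param stages list of [stage_profile()]s in cycle order (unique stage
#'   labels).
#' @param corrections list of corrections, each a list with fields
#'   `after_state` (a state label, or `"start"` to shift the whole cycle),
#'   `label`, `value` (kcal/mol) and optional `error`. The correction shifts
#'   every state after `after_state`.
#' @param irreversible_after character vector of state labels; the step
#'   leaving each named state is marked irreversible (states before it stop
#'   being accessible resting states in [effective_barrier()]).
#' @param deprotonation `"preapplied"` when the first stage's energies already
#'   include the nucleophile-deprotonation penalty (the default for printed
#'   stage tables), `"correction"` when it is supplied in `corrections`
#'   (labelled containing "deproton"), `"none"`. Supplying a deprotonation
#'   correction together with `"preapplied"` is an error (double counting).
#' @return an `assembled_cycle`: list with `states` (data.frame: `state`,
#'   `stage`, `kind`, `G`, `error`), `corrections` (with resolved positions),
#'   `irreversible` (state positions after which the step is irreversible),
#'   and `stage_labels`.
#' @export
join_stages <- function(stages, corrections = list(),
                        irreversible_after = character(),
                        deprotonation = c("preapplied", "correction", "none")) {
  deprotonation <- match.arg(deprotonation)
  if (inherits(stages, "stage_profile")) stages <- list(stages)
  labs <- vapply(stages, function(s) s$stage_label, character(1))
  if (anyDuplicated(labs)) stop("stage labels must be unique")
  all_states <- unlist(lapply(seq_along(stages), function(k) {
    labs_k <- stages[[k]]$table$label
    # a stage may share its reactant with the previous stage's product; the
    # shared state is merged at assembly time
    if (k > 1 && labs_k[1] == utils::tail(stages[[k - 1]]$table$label, 1)) {
      labs_k <- labs_k[-1]
    }
    labs_k
  }))
  if (anyDuplicated(all_states)) stop("state labels must be unique across stages")
  corr_after <- vapply(corrections, function(co) co$after_state, character(1))
  corr_lab <- vapply(corrections, function(co) co$label, character(1))
  bad <- setdiff(corr_after, c("start", all_states))
  if (length(bad)) {
    stop(sprintf("correction references unknown state(s): %s",
                 paste(bad, collapse = ", ")))
  }
  has_deprot <- any(grepl("deproton", corr_lab, ignore.case = TRUE))
  if (deprotonation == "preapplied" && has_deprot) {
    stop("deprotonation penalty is flagged preapplied AND supplied as a correction")
  }
  if (deprotonation == "correction" && !has_deprot) {
    stop("deprotonation = \"correction\" but no deprotonation-labelled correction given")
  }
  bad <- setdiff(irreversible_after, all_states)
  if (length(bad)) {
    stop(sprintf("irreversible_after references unknown state(s): %s",
                 paste(bad, collapse = ", ")))
  }

  corr_val <- vapply(corrections, function(co) co$value, numeric(1))
  corr_err <- vapply(corrections, function(co) {
    if (is.null(co$error)) 0 else co$error
  }, numeric(1))
  base <- sum(corr_val[corr_after == "start"])
  acc_err2 <- sum(corr_err[corr_after == "start"]^2)
  rows <- list(); applied <- list()
  last_abs <- NA_real_
  for (k in seq_along(stages)) {
    tb <- stages[[k]]$table
    off <- if (k == 1) base else last_abs - tb$free_energy[1]
    start_i <- 1L
    if (k > 1 &&
        tb$label[1] == utils::tail(stages[[k - 1]]$table$label, 1)) {
      start_i <- 2L  # shared junction state already emitted
    }
    for (i in seq(start_i, nrow(tb))) {
      gabs <- tb$free_energy[i] + off
      rows[[length(rows) + 1L]] <- data.frame(
        state = tb$label[i], stage = labs[k], kind = tb$kind[i], G = gabs,
        error = sqrt(tb$error[i]^2 + acc_err2), stringsAsFactors = FALSE)
      hit <- which(corr_after == tb$label[i])
      for (h in hit) {
        off <- off + corr_val[h]
        gabs <- gabs + corr_val[h]
        acc_err2 <- acc_err2 + corr_err[h]^2
        applied[[length(applied) + 1L]] <- data.frame(
          position = length(rows), label = corr_lab[h], value = corr_val[h],
          error = corr_err[h], stringsAsFactors = FALSE)
      }
      last_abs <- gabs
    }
  }
  states <- do.call(rbind, rows)
  marks <- match(irreversible_after, states$state)
  structure(list(states = states,
                 corrections = if (length(applied)) do.call(rbind, applied)
                 else data.frame(position = integer(), label = character(),
                                 value = numeric(), error = numeric()),
                 irreversible = sort(marks), stage_labels = labs,
                 deprotonation = deprotonation,
                 reference = stages[[1]]$reference),
            class = "assembled_cycle")
}

#' @export
print.assembled_cycle <- function(x, ...) {
  cat(sprintf("<assembled_cycle> %d states over stages: %s (zero = %s)\n",
              nrow(x$states), paste(x$stage_labels, collapse = " > "),
              x$reference))
  print(render_cycle_table(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Effective (rate-determining) barrier of an assembled cycle
#'
#' Scans all pairs (resting intermediate i, later transition state j) that
#' are not separated by an irreversible step and returns the maximum free
#' energy span G(TS_j) - G(I_i). An irreversible step resets the accessible
#' resting-state window: states at or before the marked position cannot serve
#' as resting states for transition states beyond it.
#'
#' @param cycle an [join_stages()] `assembled_cycle` with at least one
#'   transition state.
#' @return a `barrier_report`: list with `barrier` (kcal/mol), `error`
#'   (quadrature of the two states' errors), `determining_step` and
#'   `resting_state` labels, their positions, and the per-TS span table.
#' @export
effective_barrier <- function(cycle) {
  st <- cycle$states
  ts <- which(st$kind == "maximum")
  if (!length(ts)) stop("no transition state present in the assembled cycle")
  mins <- which(st$kind == "minimum")
  marks <- cycle$irreversible
  per_ts <- lapply(ts, function(j) {
    gate <- marks[marks < j]
    lo <- if (length(gate)) max(gate) else 0L
    allowed <- mins[mins < j & mins > lo]
    if (!length(allowed)) return(NULL)
    i <- allowed[which.min(st$G[allowed])]
    data.frame(ts = st$state[j], resting = st$state[i],
               barrier = st$G[j] - st$G[i],
               error = sqrt(st$error[j]^2 + st$error[i]^2),
               ts_position = j, resting_position = i,
               stringsAsFactors = FALSE)
  })
  per_ts <- do.call(rbind, per_ts)
  if (is.null(per_ts) || !nrow(per_ts)) {
    stop("no admissible (resting state, transition state) pair")
  }
  best <- per_ts[which.max(per_ts$barrier), ]
  structure(list(barrier = best$barrier, error = best$error,
                 determining_step = best$ts, resting_state = best$resting,
                 ts_position = best$ts_position,
                 resting_position = best$resting_position,
                 spans = per_ts),
            class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf(
    "<barrier_report> effective barrier %.2f +- %.2f kcal/mol at %s from resting state %s\n",
    x$barrier, x$error, x$determining_step, x$resting_state))
  invisible(x)
}

#' Tabular report of an assembled cycle
#'
#' One row per state with its stage, absolute free energy (relative to the
#' cycle reference), error and the step free-energy change from the previous
#' state.
#'
#' @param cycle an `assembled_cycle`.
#' @return a data.frame with columns `state`, `stage`, `kind`, `G`, `error`,
#'   `step_dG`.
#' @export
render_cycle_table <- function(cycle) {
  st <- cycle$states
  data.frame(state = st$state, stage = st$stage, kind = st$kind, G = st$G,
             error = st$error, step_dG = c(NA, diff(st$G)),
             stringsAsFactors = FALSE)
}

#' Write / read an assembled-cycle table as CSV
#'
#' Numeric columns are written with 17 significant digits so a round trip
#' reproduces the doubles bit-exactly.
#'
#' @param cycle an `assembled_cycle`.
#' @param file path.
#' @return [read_cycle_csv()] returns the table data.frame.
#' @export
write_cycle_csv <- function(cycle, file) {
  tb <- render_cycle_table(cycle)
  for (col in c("G", "error", "step_dG")) {
    tb[[col]] <- ifelse(is.na(tb[[col]]), "", sprintf("%.17g", tb[[col]]))
  }
  utils::write.csv(tb, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cycle_csv
#' @export
read_cycle_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  for (col in c("G", "error", "step_dG")) d[[col]] <- as.numeric(d[[col]])
  d
}
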