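#' Published hASNaseIII calibration data
#'
#' Stationary free energies (kcal/mol) of the catalytic cycle of human
#' asparaginase III (hASNaseIII, an Ntn-hydrolase whose N-terminal Thr168
#' provides both nucleophile and base), as reported for its QM/MM free-energy
#' profiles. These tables are the calibration targets of the synthetic
#' landscapes; the package never computes them ab initio.
#'
#' * `asnase3_acylation_spec()` — acyl-enzyme formation stage
#'   (R, TS1 ... TS4, ACE+NH3), referenced to the Michaelis complex; the
#'   reactant value 1.4 already includes the N-terminal deprotonation penalty.
#' * `asnase3_hydrolysis_spec()` — deacylation stage (ACE, TS5, I4, TS6, P),
#'   referenced to the acyl-enzyme complex.
#' * `asnase3_regeneration_spec()` — proton-transfer regeneration stage.
#'   Only the barrier (5.2) and the overall reaction free energy (-7.2
#'   relative to Michaelis) are published for this stage; the product depth
#'   (-11.23 relative to the deacylation product) is a synthetic calibration
#'   chosen so the assembled cycle ends at exactly -7.2
#'   (2.7 - 4.47 + 5.8 - 11.23 = -7.2). The backing file is accordingly named
#'   `regeneration_stations_synthetic.csv`.
#'
#' @return a [stationary_spec()].
#' @export
asnase3_acylation_spec <- function() {
  read_stationary_spec(
    system.file("extdata", "acylation_stations.csv", package = "stringfe",
                mustWork = TRUE),
    zero_reference = "Michaelis")
}

#' @rdname asnase3_acylation_spec
#' @export
asnase3_hydrolysis_spec <- function() {
  read_stationary_spec(
    system.file("extdata", "hydrolysis_stations.csv", package = "stringfe",
                mustWork = TRUE),
    zero_reference = "ACE")
}

#' @rdname asnase3_acylation_spec
#' @export
asnase3_regeneration_spec <- function() {
  read_stationary_spec(
    system.file("extdata", "regeneration_stations_synthetic.csv",
                package = "stringfe", mustWork = TRUE),
    zero_reference = "P")
}

#' Published scalar reference values for the hASNaseIII cycle
#'
#' The worked-example constants used to calibrate toy alchemical systems and
#' to assemble the catalytic cycle: ammonia-release free energy, N-terminal
#' deprotonation penalty at pH 7.5, pKa values, the acylation-stage net free
#' energy, the effective barrier and the overall reaction free energy. All in
#' kcal/mol (pKa and pH unitless, temperature in K).
#'
#' @return a named list.
#' @export
asnase3_constants <- function() {
  list(release_dG = -4.47, release_err = 0.04,
       deprotonation_penalty = 1.38, penalty_err = 0.06,
       pKa_holo = 8.5, pKa_apo = 8.6, pKa_water = 9.1, pH = 7.5,
       temperature = 310,
       acylation_net = -1.8, acylation_net_err = 0.6,
       michaelis_offset = 1.4,
       effective_barrier = 20.9, effective_barrier_err = 1.2,
       regeneration_barrier = 5.2, regeneration_barrier_err = 0.8,
       overall_dG = -7.2, overall_err = 0.6)
}
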