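Package: stringfe
Title: Adaptive String Free-Energy Workflows on Collective-Variable Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of the multiscale free-energy workflow
    used to characterise enzyme catalytic cycles on collective-variable (CV)
    landscapes: adaptive string refinement of minimum free energy paths with
    Hamiltonian neighbour exchange, path-CV umbrella sampling with on-the-fly
    force constants and WHAM reconstruction, thermodynamic-integration cycles
    for pKa shifts and ligand release, and assembly of multi-stage catalytic
    free-energy profiles with rate-determining-step identification. A synthetic
    landscape generator calibrated to prescribed stationary free energies
    stands in for the all-atom QM/MM layer so every estimator is exercisable
    with analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
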