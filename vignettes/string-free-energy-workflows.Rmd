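---
title: "Free-energy workflows on collective-variable landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy workflows on collective-variable landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringfe)
```

## Scope and model

`stringfe` implements, at desk scale, the free-energy machinery used to
characterise multi-stage enzyme mechanisms in collective-variable (CV) space:
the adaptive string method for minimum free energy paths (MFEPs), a path
collective variable, umbrella sampling with WHAM, thermodynamic-integration
(TI) cycles for pKa shifts and ligand release, and the assembly of stage
profiles into one catalytic cycle with an effective-barrier analysis.

The running example throughout the package is the catalytic cycle of human
asparaginase III (hASNaseIII), an Ntn-hydrolase whose N-terminal threonine
supplies both the nucleophile (hydroxyl) and the base (alpha-amino group).
The enzyme-scale electronic-structure free energies themselves are inputs,
not outputs: the published stationary free energies of the acylation and
deacylation stages (`asnase3_acylation_spec()`, `asnase3_hydrolysis_spec()`)
calibrate synthetic landscapes on which every estimator can be exercised and
validated against analytic oracles. Units are fixed package-wide:
kcal/mol, Angstrom, amu, Kelvin, with k_B = 0.0019872 kcal/mol/K.

## Calibrated landscapes

`make_reaction_landscape()` embeds a curve in CV space with stationary
stations at equally spaced arc-length positions (default spacing 1 A) and
builds

* a longitudinal profile through the prescribed free energies using cubic
  Hermite interpolation with zero slope clamped at every station — the
  published tables give stationary values only, so any interpolant must make
  the stations exact stationary points; the clamped Hermite is the simplest
  one that does, and
* uniform harmonic confinement transverse to the curve (default
  50 kcal/mol/A^2, a width of ~0.11 A at 310 K).

Because the transverse stiffness is uniform along the curve, the transverse
free-energy contribution is a constant: the exact potential of mean force
along the curve equals the prescribed profile plus an additive constant, for
any transverse stiffness. This transverse-entropy cancellation is asserted by
the test suite at two stiffnesses. Basin widths and curvatures on the real
enzyme surface are unknown; they are free parameters here, and the invariants
guarantee they cannot affect relative stationary energies.

The default geometry is a straight segment; a half-wave sinusoidal bend
(`geometry = "sine"`) exercises path curvature. The landscape continues as a
confining quadratic wall beyond the terminal stations so that every sampling
box is bounded.

What the synthetic landscapes deliberately do *not* emulate: multiple
competing reaction channels, transverse anharmonicity, position-dependent
diffusion, and the dimensionality (6+ CVs) of the real QM/MM surfaces. A
passing pipeline therefore demonstrates estimator correctness, not that the
method would converge equally fast on a rugged many-dimensional surface.

## Langevin sampling

`langevin_sample()` integrates underdamped Langevin dynamics with the BAOAB
splitting, which has very small configurational sampling bias at the
package's default 1 fs timestep. Defaults follow the conditions of the
emulated simulations: 310 K, collision frequency 2.0 ps^-1, 1 fs timestep;
burn-in defaults to 10% of a run. Timesteps are converted internally through
the natural time unit sqrt(amu A^2 mol/kcal) = 48.888 fs. Stiff test cases
(restraints of 1e6 kcal/mol/A^2, the canonical Mueller-Brown surface in its
own units) need proportionally finer timesteps; the tests choose them by the
usual omega*dt stability argument.

All replicas of a calculation — string nodes, umbrella windows, lambda
points x TI replicas — are advanced in lockstep as rows of one position
matrix, which is what makes the pure-R implementation fast enough. Every
stochastic operation derives its stream from a master seed and an operation
counter (`derive_seed()`), so runs are reproducible end to end.

`equilibrium_moment()` provides the deterministic Boltzmann-quadrature
oracle (dimension <= 3) against which sampled moments are validated.

## Adaptive string method

`run_string()` evolves N equidistant restrained replicas between two basins:

* the free-energy gradient at each node is estimated from the mean restraint
  displacement, g = -k (<x> - center), the harmonic identity that makes the
  estimate unbiased for any restraint strength;
* interior nodes move against the gradient component transverse to the local
  path tangent (central-difference tangent in the mass-weighted metric);
  moving only the transverse component is a documented substitute for the
  original algorithm's update, whose exact form is not restated in the
  source material;
* endpoints relax by full steepest descent, so they settle into their
  basins' minima;
* the string is reparametrised to equal mass-weighted arc length every
  iteration (piecewise-linear resampling, endpoints fixed, ties to the lower
  segment);
* Hamiltonian exchange between neighbour nodes is attempted every 50 steps
  with Metropolis acceptance on the bias-energy difference, alternating
  even/odd pairings.

Convergence follows the mass-weighted RMSD between the string and its
running average: converged when it stays below 0.1 amu^1/2 A over a trailing
window equivalent to 2 ps of sampling. Node moves are capped at half the
node spacing, with step halving (up to 10 times) if nodes would collide.
The returned string is the average over the trailing convergence window,
reparametrised once more — averaging suppresses the per-iteration sampling
noise of individual node positions. Per-CV masses define the metric;
transferred-proton CVs conventionally carry 2 amu.

Defaults: 32 nodes, node stiffness 200 kcal/mol/A^2, step size 0.01
A^2 mol/kcal, 500 sampling steps per iteration.

## Path CV and umbrella sampling

`build_path()` turns a converged string into a path CV: s(x) is the
normalised mass-weighted arc length of the nearest point on the
piecewise-linear path (ties to the lower segment index), and z the metric
distance to it. The projection-based s is exact on the path and has a simple
piecewise-constant gradient; the exponential-weighted path CV of the
literature is not needed at this scale and no transverse (z) penalty is
added. Before umbrella sampling the path is extended 0.3 amu^1/2 A beyond
each terminal basin (`extend_path()`): projection clamps s at the ends, and
without padding that pile-up lands exactly in the reactant bin and biases
the profile's zero reference.

`place_windows()` spaces window centers at c_i = (i - 1/2)/n and starts from
the flat-profile stiffness k = 4 k_B T / ds^2 (biased sd = half the window
spacing). The pipeline chooses the window count as a density, about 5.6
windows per unit of metric path length (48 on the 8.6-unit acylation
reference stage): a fixed count would make windows on short paths stiff
enough (4 k_B T / ds^2 growing with the inverse square of the spacing) to
destabilise the 1 fs integrator. A short pilot run rescales each window's stiffness by
(observed sd / target sd)^2, clipped to [1/4, 4] of the initial value, which
homogenises the sampled density along s; empty pilot windows are retried
once at fourfold stiffness. Production sampling (`umbrella_sample()`)
defaults to 1.5e5 post-burn-in steps per window. The smaller pilot-scale
default of 5e4 steps leaves the seed-to-seed spread of recovered stationary
energies above the package's own recovery tolerance on the 9-station
acylation landscape; tripling the sampling brings the spread comfortably
inside it at about three minutes per pipeline on one CPU.

## WHAM

`wham()` reconstructs the profile on 200 bins (default) over s in [0, 1].
The window free energies solve the standard self-consistent equations; the
implementation minimises the equivalent convex negative log-likelihood with
L-BFGS (analytic gradient) and then polishes with self-consistent sweeps
until the maximum change of the window free energies falls below 1e-10
(relative). Plain fixed-point iteration is not used on its own: with narrow,
stiff windows its geometric convergence rate approaches one and tens of
thousands of sweeps can still hide several tenths of a kcal/mol. The
likelihood route reaches the same fixed point directly and warm-starts
cheaply during bootstrap resampling.

The zero reference defaults to the first basin along s (the stage reactant,
the Michaelis-complex analog); `"global_min"` or a numeric s are
alternatives. Uncertainties come from a seeded block bootstrap
(`pmf_error()`, default 20 contiguous blocks per window, 100 resamples),
with every resampled profile re-zeroed by the same rule so the reference
state's own uncertainty is included. The published tables report plus/minus
values without stating their estimator; the block bootstrap is this
package's documented choice.

`extract_stationary()` reads minima and maxima off the (moving-average
smoothed, default 5 bins) profile and prunes features of prominence below
0.5 kcal/mol, keeping strict alternation; on padded profiles the confinement
walls appear as boundary maxima and are trimmed by the pipeline. Smoothing
trades a small curvature bias (about 0.1 kcal/mol at the sharpest calibrated
stations) for robustness of peak values against bin noise.

## Thermodynamic integration and cycles

`ti_estimate()` samples dU/dlambda = V_B - V_A under the linear mixture at
11 equidistant lambda points (default; the source states the integration
method but not the schedule) in 5 independent replicas, integrates each
replica by the trapezoidal rule, and reports the replica mean. The error
model combines the standard error over replicas with a trapezoid-truncation
estimate (trapezoid vs natural-spline integral of the mean curve) in
quadrature — documented here because the emulated study reports errors
without stating their estimator. Toy end states are everywhere finite, so no
soft-core treatment is needed.

Two-leg cycles connect the legs to observables:

* `pka_from_cycle()`: pKa = pKa_aq + (dG_env - dG_aq) / (RT ln 10), with the
  aqueous reference 9.1 for free threonine;
* `deprotonation_penalty()`: RT ln10 (pKa - pH); at 310 K and pH 7.5 the
  formula gives 1.42 kcal/mol for pKa 8.5, while the published penalty is
  1.38 +- 0.06 — the difference is consistent with an unrounded pKa near
  8.47, and the calibrated pKa toy therefore targets the published 1.38, not
  the rounded-pKa arithmetic;
* `release_dg()`: dG_site - dG_bulk for the site-vs-bulk annihilation cycle,
  calibrated in the release toy so the analytic difference is exact by
  construction.

## Cycle assembly and the effective barrier

`join_stages()` concatenates stage stationary tables, offsetting each stage
so its reactant matches the previous (corrected) product, inserting scalar
corrections after named states (ammonia release after the acyl-enzyme +
ammonia state; optionally the deprotonation penalty at the start). A stage
may share its reactant label with the previous product, in which case the
state is merged. The deprotonation penalty may arrive pre-applied inside the
first stage's energies (as in the published acylation table, whose reactant
sits at 1.4) or as an explicit correction; a flag records which, and
supplying both is an error. Irreversibility is an explicit user mark, never
inferred: the ammonia-release step is marked by the caller.

`effective_barrier()` scans all (resting minimum, later transition state)
pairs not separated by an irreversible mark and returns the maximal span;
marks reset the accessible resting-state window, which is what makes the
second deacylation barrier (20.9 kcal/mol measured from the acyl-enzyme,
not from the deeper pre-release states) the rate-determining one in the
assembled cycle. An exhaustive-enumeration oracle checks the scan exactly on
1000 random cycles.

The regeneration stage has only two published numbers (barrier 5.2, overall
-7.2 relative to Michaelis); its fixture is synthetic beyond those, with the
product depth chosen so the assembled cycle ends at exactly -7.2.

## Trajectory descriptors

`rmsf()`, `rmsd_to_reference()` (weighted CV-space distance, no
superposition) and `state_density_2d()` (periodic-aware 2-D histograms for
distance-vs-dihedral maps, degrees in [-180, 180)) replicate the classical
trajectory analyses on CV series. ON/OFF-type state assignment is left to
user-supplied thresholds — the source figures draw that boundary visually,
so none is hard-coded. `make_ou_series()` generates exact stationary
Ornstein-Uhlenbeck fixtures with equipartition variance k_B T / k.

## Numerical choices and limitations

* Degenerate inputs are rejected with diagnostics: non-alternating
  stationary specs, saddles not above flanking minima, coincident string
  endpoints, non-overlapping umbrella windows (named), non-finite positions
  (with the walker position).
* WHAM bins with no samples propagate as NA rather than fabricated values.
* The string's step-size halving and move cap prevent node collisions but do
  not guarantee a globally optimal path on surfaces with competing channels;
  the Mueller-Brown test shows the intended behaviour on the canonical
  rugged 2-D case.
* Bootstrap errors reflect sampling noise given the realised windows; they
  do not include pilot-calibration variability between reruns.
* TI error bars inherit the t-distribution of a 5-replica standard error;
  3-SE checks therefore have slightly heavier tails than Gaussian 3-sigma.

## Problem sizes used by the tests and the acceptance script

The calibrated pipelines run with the package defaults: 32 string nodes at
500 steps per iteration, ~5.6 umbrella windows per metric path unit (48 on
the acylation stage) at 1.5e5 post-burn-in steps each, 200 WHAM bins, 100
bootstrap resamples; TI legs use 11 lambda points x 5 replicas x 2e4 steps.
On one CPU a full landscape pipeline takes one to three minutes and a TI
cycle under a minute.
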