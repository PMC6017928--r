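---
title: "Models and numerical methods in nitroredscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nitroredscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroredscope)
```

`nitroredscope` bundles the five quantitative analyses used to
characterise flavin-dependent nitroreductases and their nitroaromatic
substrates. This vignette records the model behind each stage, the
assumptions it rests on, the tunable parameters and their defaults, and
the numerical choices made where the procedure left room for judgement.

## Calibrated reduction potentials

**Model.** The one-electron reduction potential of a nitroaromatic is
obtained relative to nitrobenzene through the isodesmic electron-exchange
reaction ArNO~2~ + BzNO~2~^−•^ → ArNO~2~^−•^ + BzNO~2~:

$$\Delta G^\circ_{rxn} = G^\circ_{ArNO_2^-} + G^\circ_{BzNO_2}
  - G^\circ_{ArNO_2} - G^\circ_{BzNO_2^-},$$

followed by $E^\circ = -\Delta G^\circ / nF$ anchored at the experimental
nitrobenzene couple. Because both sides of the exchange contain one
neutral and one radical anion of similar size, systematic
electronic-structure errors largely cancel — the central assumption of
the isodesmic approach.

**Units.** Input free energies are in hartree. For a one-electron couple
the Faraday constant cancels when the energy is expressed in eV per
electron, so the conversion is a single multiplication by
27.2114 eV/hartree; `potential_from_dg()` is exactly affine with slope
−27.2114 V per hartree. The reference default is
$E^{\circ\prime}_{BzNO_2} = -0.486$ V vs NHE (pH 7), replaceable via
`reference_couple()`.

**Conformers.** When several records share a (compound, state) pair they
are treated as alternative conformers and the lowest-energy one is
retained — the conventional retention rule after a conformer search.
Truncating large substituents before computation (e.g. replacing a long
alkyl amine with NH~2~) is data preparation upstream of this package.

**Calibration.** Gas-phase energies with modest basis sets neglect the
aqueous dielectric that stabilises the radical anion, so raw computed
potentials need an empirical linear map onto the experimental scale. The
package fits `Comp = s·(Exp + b)` by ordinary least squares of the
computed value on the experimental one and re-parameterises
(`b = intercept/s`). Regressing Comp on Exp (rather than the reverse) was
an open choice; it was adopted because it matches the stated form of the
map and makes the re-parameterisation unique and reproducible — with tight
scatter the two directions agree closely anyway. `mad_after` (mean
absolute deviation of back-transformed potentials from experiment, in V)
is the figure of merit; it equals `mean(|residual|)/|s|` exactly, which
the tests verify by brute force. Degenerate inputs (fewer than two pairs,
zero variance in Exp) are errors, not warnings.

## Enzyme kinetics

**Initial velocities.** `initial_velocity()` fits a line to the early
part of an absorbance trace, subtracts the background (uncoupled
co-substrate oxidation) slope, and converts through Beer–Lambert with the
user's extinction coefficient (2660 M^−1^cm^−1^ at 370 nm for NADH is
typical). The fitted window is the first 10% of points (minimum 4) — the
conventional initial-rate practice — with a curvature guard: a quadratic
is fitted to the candidate window and the window shrinks by a quarter at
a time while the quadratic term contributes more than 5% of the linear
change across it. Both the fraction and the tolerance are arguments.
Velocities are floored at zero: a trace flatter than its baseline carries
no rate information.

**Michaelis–Menten.** `fit_michaelis_menten()` fits
$v = k_{cat}[E]_0[S]/(K_M+[S])$ on the normalised rate $v/[E]_0$ by
Levenberg–Marquardt least squares with positivity bounds, started from a
Hanes–Woolf linearisation ($S/v$ vs $S$), which is robust for
hyperbolic data and removes any starting-value guesswork. Weighting is
unweighted by default with an optional `1/v` relative weighting. The fit
is invariant to row order and to unit-consistent rescaling (KM follows
the substrate unit; kcat does not), which the tests check numerically.
The model is the apparent single-substrate form: ping-pong bisubstrate
global fitting is out of scope.

**Hammett analysis.** `hammett_regression()` works in log base 10, the
physical-organic convention. The linear free-energy relationship
$\log_{10}(Y_i/Y_0) = \rho\sigma$ has no intercept, so in normalised mode
(each rate divided by the parent, σ = 0) the regression is constrained
through the origin — this is the default. A free-intercept mode on
$\log_{10}(Y_i)$ is provided for series where normalisation to a parent
is not wanted or where an intercept is itself of interest; which mode a
published ρ used is often unstated, so both are exposed. σ values are
user-supplied; `sigma_para_table()` ships standard literature σ~para~
constants for convenience.

## Dye-referenced redox titration

**Model.** In a slow xanthine/xanthine-oxidase reduction with a mediator
present, the enzyme and the indicator dye stay at a common solution
potential, so their Nernst equations combine into

$$\log\frac{E_{red}}{E_{ox}} = \frac{n_e}{n_d}\log\frac{D_{red}}{D_{ox}}
  + \frac{n_e\,(E^\circ_e - E^\circ_d)}{0.0592},$$

a line whose slope (1 for two 2-electron couples) verifies Nernstian
equilibrium and whose intercept yields the enzyme midpoint
$E^\circ_e = E^\circ_d + \mathrm{intercept}\times 0.0592/n_e$. The
0.0592 V constant fixes the analysis at 25 °C. Equilibrium at every
recorded point is assumed; reduction kinetics are not modelled.

**Spectral bookkeeping.** The oxidized dye concentration comes directly
from A521 (phenosafranine defaults: ε~521~ = 44.7, ε~454~ =
9.85 mM^−1^cm^−1^, E°~d~ = −252 mV, n~d~ = 2, 18 µM total); its small
A454 contribution is subtracted before the enzyme's oxidized fraction is
computed. Because no absolute enzyme extinction coefficient is assumed,
the enzyme fraction is normalised between the dye-corrected endpoint
absorbances, which the caller supplies explicitly — endpoint
normalisation is the only closed procedure when ε~454~ of the enzyme is
unknown. Both fractions are clipped to their physical ranges to absorb
photometric noise at the extremes.

**Interior window.** Log-ratios blow up when either couple approaches
full oxidation or reduction, so only points with both fractions in
(0.02, 0.98) enter the regression (configurable); excluded points are
counted in the result. At least 3 interior points are required —
otherwise the titration does not bracket both midpoints and the fit
aborts with that diagnosis.

## Reduction-product masses

The reduction ladder is pure formula arithmetic on one nitro group:
nitroso = parent − O, hydroxylamine = parent − O + 2H, amine = parent −
2O + 2H, giving nominal deltas of −16, −14 and −30 Da, which hold for
every parent with N ≥ 1 and O ≥ 2 (a property test sweeps random
formulas). Ion m/z are reported as nominal ± 1 under the
nearest-integer convention, which matches the printed precision of
published LC-MS tables; monoisotopic masses are also returned and round
to the nominal values for all compounds of interest here. Exactly one
nitro group is reduced per call — regioselectivity on polynitro parents
is chemistry, not mass arithmetic. The detection policy encodes the yield
bookkeeping of a calibrated LC-MS method: amine formed above 1% of
substrate is always detected, and non-detection bounds the yield below
0.5%; yields between the two are indeterminate.

## Surface areas and volumes

**SASA.** `sasa()` is a Shrake–Rupley-style implementation of the
Lee–Richards accessible surface: each atom's sphere is expanded by the
probe radius (default 1.4 Å, water) and sampled with a deterministic
Fibonacci lattice (default 960 points); points inside any neighbour's
expanded sphere are occluded. The lattice uses no RNG, so areas are
bit-stable across runs; the price is that results are only
rotation-invariant to sampling tolerance (~1% at 960 points), which a
test quantifies. Correctness anchors: the isolated sphere (exact closed
form), the two-sphere spherical-cap formula (analytic oracle), a
convergence check at 60/240/960 points, and agreement within 2% with an
independent implementation (biotite's `sasa`, run with identical radii,
probe and point count).

**Buried interface.** `buried_interface()` computes each chain's SASA in
isolation and in the complex and applies
$\{ASA(A)+ASA(B)-ASA(AB)\}/2$, reporting also the buried percentage of
the monomer surface. Chains are taken as deposited — assembly
reconstruction from symmetry operators is out of scope, so the user must
supply a file containing the biological dimer.

**Radii.** The van der Waals set is C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å (plus halogens and common ions), with a 1.8 Å fallback and
warning for unknown elements. Published per-structure areas computed with
other viewers' (unenumerated) radii sets should therefore be reproduced
to within a few percent, not exactly. Hydrogens are excluded by default,
matching crystal structures that lack them.

**CPK volume.** The union volume of the van der Waals spheres is
integrated on a deterministic cubic grid (default spacing 0.2 Å, ~1%
accuracy for small molecules), validated against the sphere and
two-sphere lens closed forms.

## Synthetic data: what it does and does not show

Each generator produces data with exactly the statistical structure its
consuming stage assumes: linear computed-vs-experimental pairs with
additive Gaussian scatter (defaults: slope 4.67, offset 0.379 V, σ =
0.02 V, 12 pairs); Michaelis–Menten rates on 8 log-spaced concentrations
over 0.013–0.5 mM with mean-one multiplicative lognormal noise (rates are
strictly positive, so lognormal rather than Gaussian); Hammett series on
a standard σ grid spanning −0.27 to 0.78; titrations built by sweeping
the solution potential across both midpoints and pushing each couple's
Nernst fraction through the spectral model (81 points, so that a typical
run leaves ~13–17 points in the interior window); and mirrored toy atom
clusters for the surface machinery. Generators take a single seed, use an
independent RNG stream via `withr::with_seed`, and leave the caller's RNG
state untouched, so adding a generator never perturbs existing fixtures.

Passing recovery tests on these data shows that the estimators are
correct and unbiased *under the assumed noise model*. Real instrument
data add what the generators deliberately omit: baseline drift and lamp
noise in traces, substrate depletion during the "initial" window,
mediator-coupling failures and spectral overlap in titrations, and
heteroscedastic rate errors. Recovery tolerances used in the tests
(calibration slope under σ = 0.02 V noise; ρ mean within 0.1 over 50
replicates at 10% noise; k~cat~ within 10% at 5% noise; midpoint within
±30 mV at 1% absorbance noise — the spread a careful titration is
typically quoted at) are statements about the fitting machinery, not
about any particular enzyme.

## Problem sizes and runtime choices

The test suite runs parameter-recovery loops at sizes chosen to make the
statistical assertions stable while keeping the whole suite fast on one
CPU: 20 seed replicates per sample size for calibration convergence
(n = 10/100/1000), 50 replicates for the Hammett bias check, 20 for the
titration midpoint, and toy structures of 20–50 atoms for the surface
oracles (where closed forms, not size, provide the power). The SASA
convergence and oracle comparisons use 960 points, the package default.

## Known limitations

- Electrochemistry is single-couple and pH-implicit: no semiquinone
  intermediates, no multi-electron pH-dependent schemes, no continuum
  solvation — the calibration absorbs solvent effects empirically.
- The kinetic layer fits apparent single-substrate parameters; bisubstrate
  mechanisms need a dedicated global fit.
- The titration reduction requires user-supplied endpoint absorbances and
  assumes full equilibration at every point.
- Mass prediction covers elements C, H, N, O, S, F, P, Cl, Br, I, ignores
  isotope envelopes and fragmentation, and reduces one nitro group at a
  time.
- SASA/volume are sampling/grid methods: deterministic and validated, but
  carrying ~1% discretisation error at default resolution, plus the
  radii-set dependence noted above.
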