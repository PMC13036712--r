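---
title: "Models and methods behind supraspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind supraspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supraspec)
```

supraspec implements the quantitative workflow of a supramolecular
fluorescence-sensing study: a dye (the *indicator*) binds a macrocyclic
host such as cucurbit[7]uril, switching on its emission; an analyte (the
*competitor*) displaces it, switching the emission off again. The package
covers the binding thermodynamics, the photophysics used to characterize
free and complexed dye, the conversion of computed electronic excitations
into UV-vis spectra, electron-density topology descriptors of the
host-guest contacts, and solvation-shell statistics from trajectories.
This vignette explains each model, its assumptions, and the numerical
choices — in particular where the design was genuinely open.

## Binding equilibria

**1:1 association.** For totals $H_T$, $I_T$ and association constant
$K_1$, the complex concentration is the smaller root of

$$x^2 - \left(H_T + I_T + \tfrac{1}{K_1}\right)x + H_T I_T = 0 ,$$

evaluated in the cancellation-free form $x = 2H_T I_T/(b + \sqrt{b^2 -
4H_TI_T})$ so weak- and strong-binding limits are equally accurate. The
smaller root is the only one keeping every species inside $[0,
\min(H_T, I_T)]$. $K_1 = 0$ means no binding; $K_1 = \infty$ is accepted
as the stoichiometric limit.

**Competitive displacement.** With a competitor $G$ (constants $K_1$ for
the indicator, $K_2$ for the competitor), the closed cubic in the complex
concentration is error-prone to transcribe; `solve_competitive()` instead
solves the exact mass balance as a scalar root problem in the free host
concentration $h$:

$$h\left(1 + \frac{K_1 I_T}{1 + K_1 h} + \frac{K_2 G_T}{1 + K_2 h}\right) = H_T .$$

The left side is strictly increasing in $h$, so the physical root is
unique in $[0, H_T]$; it is bracketed by bisection and polished by Newton
steps, and the returned state satisfies all five defining equations
(two equilibrium quotients, three balances) to better than $10^{-10}$
relative. The test suite cross-checks it against an independent damped
fixed-point iteration on the free concentrations.

**Signal model.** Fluorescence intensity is taken linear in the emitting
species, $S = a_{\mathrm{free}}\,[I] + a_{\mathrm{complex}}\,[HI]$,
because the free dye retains residual emission while the complex is
brighter. A pure complex-only response is available with
`signal_model = "complex-only"`.

**Fitting.** `fit_1to1()` and `fit_ida()` optimize $\log_{10} K$ — the
natural, scale-free parameterization over the $10^3$–$10^9\;
\mathrm{M^{-1}}$ range relevant to cucurbituril hosts — while the two
signal coefficients, which enter linearly, are profiled out by least
squares at every candidate $K$ (variable projection). The profile is
scanned on a coarse $\log_{10} K$ grid covering $10^0$–$10^{12}$ and
refined with Brent's method, which removes any dependence on starting
values. Uncertainty comes from a residual bootstrap (resample residuals,
add to the fitted curve, refit; percentile interval), with a mandatory
seed recorded in the result: the experimental convention behind a bare
"±" on a binding constant is often ambiguous, and a bootstrap interval is
explicit about what it measures. `n_boot = 0` gives the deterministic fit
alone.

**Thermodynamics.** `gibbs_from_k()` applies $\Delta G = -RT\ln K$ with
$R = 1.98720425\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}}$, and
`thermo_consistency()` closes $\Delta G = \Delta H - T\Delta S$ for
calorimetric bookkeeping. No calorimeter power-curve fitting is done
here.

## Photophysics

**Quantum yield.** The relative (reference-slope) method:
$\phi = \phi_{ref}\,(m_s/m_{ref})\,(n_s^2/n_{ref}^2)$, where $m$ is the
slope of integrated emission versus absorbance across a dilution series
(`qy_gradient()`, through the origin by default) and $n$ are refractive
indices, defaulting to equal — the same-solvent case. Values above 1
warn rather than error: they indicate an inconsistent reference, not an
arithmetic fault.

**Lifetime reconvolution.** A TCSPC histogram is modeled as the
convolution of $\sum_i a_i e^{-t/\tau_i}$ with the measured instrument
response function, plus a constant background. The convolution is
*periodic* on the acquisition window: TCSPC excitation is repetitive, so
intensity leaving the window re-enters at the start, and a unit-sum
kernel then conserves total counts exactly — a property the tests rely
on. The IRF shift is a continuous fitted parameter applied by linear
interpolation of the IRF histogram. The default objective is weighted
least squares with Poisson weights $1/\max(y_j, 1)$, standard TCSPC
practice and robust at desk scale; an exact Poisson maximum-likelihood
refinement is available with `objective = "mle"`. Lifetimes are
log-parameterized inside a Levenberg-Marquardt loop; amplitudes and
background, which enter linearly, are solved by weighted least squares
with a nonnegativity clamp at each step. Randomized multi-starts
(seeded) protect the 2- and 3-component fits from local minima. The
number of components is user-chosen; the reduced chi-square is reported
so the user can compare fits, since component counts should be a
scientific decision, not an automatic one. Fractional intensities are
$f_i = a_i\tau_i / \sum_j a_j\tau_j$.

## Spectra

Each electronic transition at wavenumber $\nu'_{i\to f}$ with oscillator
strength $f$ contributes a Gaussian band

$$\varepsilon(\nu') = \frac{2.175\times10^{8}}{\Delta\nu'_{1/2}}\, f\,
\exp\!\left(-2.772\,\frac{(\nu'-\nu'_{i\to f})^2}{\Delta\nu_{1/2}'^2}\right)$$

in $\mathrm{M^{-1}cm^{-1}}$, with the default FWHM of 3000 cm$^{-1}$
typical for solution UV-vis. The two literal constants (2.175×10⁸, and
2.772 ≈ 4 ln 2) are used exactly as conventionally printed rather than
re-derived at higher precision, so spectra match the standard convolution
to the digit. Spectra live on a wavenumber grid (default 10,000–50,000
cm$^{-1}$ at 10 cm$^{-1}$), where the band shape is defined; wavelength
views are conversions of the output. Unit conversions use $\nu'
= 10^7/\lambda$ and $E = 1239.842/\lambda$ (eV, nm). Transition dipoles
follow the atomic-unit length-gauge identity $f = \tfrac{2}{3}\Delta E
|M|^2$ ($\Delta E$ in hartree): printed prefactor forms of this relation
vary and are not dimensionally reliable, whereas this identity is.
`ensemble_stats()` convolves each thermal snapshot inside a wavelength
window, records the per-snapshot maximum, and reports the population
(not sample) mean and standard deviation, matching how ensemble spreads
are usually quoted. `molar_absorptivity()` is a zero-intercept
Beer-Lambert slope divided by the path length.

## Electron-density topology

The density source is a deliberately minimal Gaussian-primitive
wavefunction model: contracted s-type primitives, an MO coefficient
matrix, and occupation numbers, read/written as a small keyed text
format. This realizes the single-determinant case where the natural
orbitals are the occupied orbitals; it is *not* a DFT wavefunction, and
the packaged dimers are synthetic model densities (the noncovalent one is
named accordingly). Full QTAIM on a real host-guest wavefunction would
require the original electronic-structure output, which cannot be
regenerated here; the machinery, however, is exact for the models it
accepts.

All field quantities are analytic: $\rho = \sum_i \eta_i|\varphi_i|^2$
with closed-form gradients and Hessians, kinetic energy density
$G = \tfrac12\sum_i \eta_i|\nabla\varphi_i|^2$, the local virial relation
$V = \tfrac14\nabla^2\rho - 2G$, total energy density $H = G + V$, and
the reduced density gradient $s = |\nabla\rho| / (2(3\pi^2)^{1/3}
\rho^{4/3})$. Atomic units throughout; Å↔bohr (0.529177210903) only at
I/O.

**Critical points.** `find_bcps()` runs a Newton search on $\nabla\rho$
seeded at bond midpoints (the contacts of interest are bonded pairs),
with step halving whenever a step increases $|\nabla\rho|$, a $10^{-10}$
gradient tolerance, 100-iteration cap, and 10⁻⁴ bohr merge radius for
duplicates. Signatures come from Hessian eigenvalue signs with a
$10^{-10}$ zero threshold; a pair that fails to converge is reported
absent, not an error. Classification at a (3,−1) point follows the
closed-shell criteria: noncovalent iff $\nabla^2\rho > 0$, $H > 0$ and
$-G/V > 1$. The linear hydrogen-bond energy estimator
$B_E = -223.08\,\rho_{BCP} + 0.7423$ kcal/mol applies in its calibration
window of roughly 0.002–0.04 e·$a_0^{-3}$ and warns outside it.

**NCI grids.** `nci_grid()` tabulates $s$ and
$\mathrm{sign}(\lambda_2)\rho$ per voxel, masking $\rho > 0.05$
e·$a_0^{-3}$ (the density scale above which gradients no longer signal
noncovalent contacts) and clamping the exported color field to
$[-0.05, 0.01]$. The middle Hessian eigenvalue is computed with a
vectorized closed-form symmetric 3×3 eigensolver so large grids stay
cheap. The RDG *isovalue* used for display is a viewer-side choice
(conventions in the literature range from 0.3 to 0.7); the full $s$
field is exported so any isovalue can be drawn.

## Solvation statistics

Orthorhombic boxes with the minimum-image convention throughout.
`rdf()` is the standard pair histogram normalized by exact ideal-gas
shell counts $\rho_B\,\tfrac{4}{3}\pi(r_2^3 - r_1^3)$ per reference atom.
`first_shell()` finds the first interior maximum and following minimum on
a 3-point moving average of $g(r)$ (raw-g detection available) — bin
noise otherwise fragments flat peaks — while the coordination integral
always uses the raw histogram with exact shell volumes, so a planted
shell of $N$ molecules integrates to exactly $N$.

Hydrogen bonds use two geometric cutoffs: heavy-atom (acceptor-donor)
distance ≤ 3.5 Å and an acceptor-donor-hydrogen angle ≤ 30°. The vertex
of that angle is a genuine ambiguity in common notation; here it is the
angle *at the donor* between the donor→acceptor and donor→hydrogen
directions, so small angles mean a near-linear D–H···A geometry. A
hydrogen-vertex linearity-deviation convention is available via
`hbond_criteria(vertex = "hydrogen")`.

`extract_nanodroplet()` keeps waters whose center of mass (O 15.999,
H 1.008) lies within the cutoff (default 20 Å) of the *unweighted
geometric center* of the solute — the center convention, rather than
nearest-atom distance, matching how such spherical extractions are
defined — and tags retained waters hydrogen-bonded to the solute (either
direction) as `qm`, the rest `mm`; the two sets always partition the
retained set. `occupancy_map()` counts wrapped positions per voxel, with
optional per-frame recentering on a solute selection.

## Synthetic data: what it emulates, and what it does not

Every pipeline input has a seeded generator, each a pure function of
(parameters, seed) that leaves the caller's RNG untouched.

* `gen_titration()` emulates a host-into-dye fluorescence titration:
  fixed indicator (1.16 μM), host swept 0–90 μM, association constant
  near 5×10⁵ M⁻¹, multiplicative Gaussian noise (the shot-dominated
  regime at high photon counts). The default 19-point schedule spaces
  additions finely below 10 μM: with ~1 μM dye and $K \sim 5\times10^5$
  the binding transition sits near $1/K \approx 2$ μM, and a uniform
  sweep would waste almost every point on the saturated plateau — the
  front-loaded schedule is how such titrations are actually run.
* `gen_ida()` emulates the displacement experiment: fixed host and
  indicator, competitor swept 8–1500 μM (log-spaced). The source
  experiment's host/indicator totals are not stated; 10 μM host with
  1 μM indicator gives a mostly-complexed starting point with a full
  switch-off across the sweep.
* `gen_decay()` emulates TCSPC acquisition: expectation =
  reconvolution of the planted multi-exponential with a Gaussian IRF,
  scaled to 10,000 peak counts, then Poisson-sampled per bin. The IRF
  histogram itself is written noise-free; real measured IRFs carry their
  own counting noise, which is deliberately excluded so lifetime-recovery
  tests isolate decay-channel statistics.
* `gen_excitation_ensemble()` jitters band positions in the wavelength
  domain (σ default 6 nm) and oscillator strengths (floored at 0),
  emulating thermal snapshot-to-snapshot variation. It does not model
  correlated shifts between bands or non-Gaussian tails.
* `gen_solvation_frames()` plants waters at prescribed
  distances/angles around a two-atom donor site and fills the box with
  uniformly placed waters (≥2.5 Å separation, outside a 4 Å exclusion
  zone). It makes no attempt at realistic water structure beyond the
  planted features — no O–O correlation, no orientational order — so
  passing tests demonstrate that the *analysis* recovers planted
  geometry exactly, not that the generator reproduces water physics.

Because the generators share the forward models with the fitters (by
construction: the round-trip property is the point), agreement on
synthetic data shows internal consistency plus correct noise handling;
it cannot detect model misspecification against real instruments
(IRF afterpulsing, pile-up, inner-filter effects, dye aggregation).

## Numerical choices and degenerate inputs

* Equilibrium solvers: bisection bracket then Newton polish; residual
  checked against $10^{-10}$ relative before returning. Zero host, zero
  constants and infinite $K$ are exact special cases.
* Flat titrations raise an identifiability error, as does a competitor
  sweep that leaves the complex span below 0.1%.
* Lifetime fits warn when adjacent components come within 15% of each
  other (near-degenerate Hessian territory).
* Quadrature (`integrate_density`) uses a midpoint rule on a 0.25 bohr
  grid with 7 bohr padding — sufficient for the packaged exponent range
  (≥0.35 bohr⁻²) to reach 0.1% on the electron count.
* Test problem sizes: 10⁴ random draws for the 1:1 oracle comparison,
  10³ for the competitive oracle, 20 replicates for the lifetime
  bias/RMSE check, 300 waters × 40 frames for the ideal-gas RDF — sizes
  chosen so each statistical check sits well inside its tolerance band.

## Known limitations

* 1:1 stoichiometry only; no n:m complexes, no global multi-wavelength
  fits, no ITC power curves.
* s-type Gaussians only in the wavefunction model: no p/d angular
  momentum, no ECPs, no vendor wavefunction formats, no basin
  integration.
* Orthorhombic boxes only; no triclinic minimum image.
* The bootstrap interval reflects residual resampling under a fixed
  design; it does not propagate uncertainty in the fixed $K_1$ of an IDA
  fit.
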