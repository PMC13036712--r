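# supraspec

Analysis toolkit for supramolecular fluorescence sensing with
host–guest chemistry: a fluorescent dye (indicator) binds a macrocyclic
host such as cucurbit[7]uril (CB7) and lights up; an analyte with its
own affinity for the host displaces the dye and switches the signal off
(an indicator displacement assay, IDA). supraspec implements the full
quantitative chain of such a study for experimentalists and
computational chemists:

* **Binding equilibria** — exact 1:1 and competitive mass-balance
  solvers; binding-constant fits with bootstrap intervals; ΔG/ΔH/TΔS
  bookkeeping.
* **Photophysics** — relative quantum yields by the reference-slope
  method; fluorescence lifetimes by iterative reconvolution of
  multi-exponential decays with a measured IRF.
* **Spectra** — Gaussian convolution of computed electronic excitation
  tables into UV-vis spectra; unit conversions; oscillator
  strength ↔ transition dipole; snapshot-ensemble statistics;
  Beer–Lambert molar absorptivity.
* **Electron-density topology** — QTAIM descriptors (ρ, ∇²ρ, G, V, H,
  RDG) on Gaussian-primitive model wavefunctions; bond-critical-point
  search and closed-shell classification; a linear H-bond energy
  estimator; NCI grids exported as cube files.
* **Solvation analysis** — RDFs with first-shell coordination numbers,
  geometric hydrogen-bond selection, nanodroplet (QM/MM) extraction,
  3D occupancy maps from XYZ trajectories.
* **Synthetic data** — seeded generators for every input, so the whole
  pipeline round-trips without external data.

## The core models

**1:1 binding.** The complex concentration is the smaller root of

```
[HI]² − ([H]T + [I]T + 1/K₁)[HI] + [H]T[I]T = 0 ,
```

and the measured signal is linear in the emitting species,
`S = a_free·[I] + a_complex·[HI]`. `fit_1to1()` estimates `log10 K₁`
with the signal coefficients profiled out by linear least squares at
each candidate K (variable projection).

**Competitive IDA.** With a competitor G (constant K₂), the exact
three-species mass balance reduces to a single monotone equation in the
free host concentration h:

```
h · (1 + K₁[I]T/(1 + K₁h) + K₂[G]T/(1 + K₂h)) = [H]T ,
```

solved to machine precision. `fit_ida()` estimates K₂ with K₁ fixed at
its independently fitted value.

**Lifetimes.** Expected counts are the periodic convolution of
`Σ aᵢ exp(−t/τᵢ)` with the unit-normalized, shift-interpolated IRF plus
background, fitted by Poisson-weighted least squares
(Levenberg–Marquardt over log-lifetimes and shift). Fractional
intensities are `fᵢ = aᵢτᵢ/Σ aⱼτⱼ`.

**Spectra.** Each transition contributes
`ε(ν′) = (2.175·10⁸/Δν′₁/₂)·f·exp(−2.772(ν′−ν′ᵢ→f)²/Δν′₁/₂²)` in
M⁻¹cm⁻¹ (default FWHM 3000 cm⁻¹).

**QTAIM.** From ρ and its analytic derivatives: `G = ½Σηᵢ|∇φᵢ|²`,
`V = ¼∇²ρ − 2G`, `H = G + V`, `s = |∇ρ|/(2(3π²)^⅓ρ^{4/3})`. A (3,−1)
critical point is noncovalent iff `∇²ρ > 0`, `H > 0` and `−G/V > 1`;
H-bond energies follow `B_E = −223.08·ρ_BCP + 0.7423` kcal/mol.

## Worked example

Simulate a noisy host titration at K = 4.54×10⁵ M⁻¹ (1.16 μM dye,
0–90 μM host, 1% noise), fit it, and convert to a free energy:

```r
library(supraspec)
ser <- gen_titration(K = 4.54e5, noise_sd = 0.01, seed = 42)
fit <- fit_1to1(ser, n_boot = 200, seed = 1)
fit
#> 1:1 host-guest binding fit
#>   K = 4.883e+05 M^-1  [4.509e+05, 5.229e+05] (bootstrap 200, seed 1)
#>   signal coefficients: free 2.066e+06, complex 9.729e+06 (per M)
#>   residual norm: 0.5211
gibbs_from_k(fit$K_hat, 298)
#> [1] -7.76
```

The fitted constant lands within 8% of the generating value at this
noise level, the bootstrap interval covers it, and the signal
coefficients recover the generating brightness ratio (~4.7× brighter
complex). Displacement by a competitor, with K₁ fixed from above:

```r
ida  <- gen_ida(K1 = 4.54e5, K2 = 5.5e5, noise_sd = 0.02, seed = 42)
fit_ida(ida, K1_fixed = fit$K_hat, n_boot = 200, seed = 1)
#> competitive IDA binding fit
#>   K = 5.947e+05 M^-1  [5.472e+05, 6.521e+05] (bootstrap 200, seed 1)
```

Lifetime analysis of a synthetic two-component TCSPC trace (0.59 ns
quenched dye / 4.87 ns complexed dye, 4%/96% planted fractions, 10,000
peak counts):

```r
tr <- gen_decay(lifetimes = c(0.59, 4.87), fractions = c(0.04, 0.96), seed = 42)
fit_reconvolution(tr, n_components = 2, seed = 1)
#> Reconvolution fit, 2 component(s)
#>   tau_1 = 0.5749 ns   amplitude 2874   f = 3.9%
#>   tau_2 = 4.849 ns   amplitude 8382   f = 96.1%
#>   reduced chi-square: 1.055
```

Topology of the packaged (synthetic) noncovalent dimer model:

```r
wfn <- read_wfn(system.file("extdata", "noncovalent_dimer_synthetic.wfn",
                            package = "supraspec"))
cp_report(find_bcps(wfn))[, c("rho", "H", "mGV", "class", "BE_kcal")]
#>      rho      H      mGV       class   BE_kcal
#> 0.010804 0.0260 1.879258 noncovalent -1.667775
```

The single intermolecular critical point shows the closed-shell
pattern (positive total energy density, −G/V > 1) at a density in the
hydrogen-bond range, mapping to about −1.7 kcal/mol.

## Command line

A thin umbrella CLI wraps the exported functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "supraspec", package = "supraspec"))')
Rscript $CLI simulate titration --seed 5 --out tit.csv
Rscript $CLI fit-binding tit.csv --n-boot 200 --seed 2
Rscript $CLI lifetime decay.txt irf.txt --components 2 --seed 3
Rscript $CLI rdf traj.xyz --sel-a SD --sel-b OW
```

Subcommands: `fit-binding`, `fit-ida`, `lifetime`, `qy`, `spectrum`,
`cps`, `nci`, `rdf`, `hbonds`, `droplet`, `density-map`, `simulate`.
Results are JSON on stdout (curves as CSV, grids as cube files); a YAML
`--config` file can hold per-subcommand defaults, with explicit flags
taking precedence.

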