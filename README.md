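# sascontrast

Contrast-variation small-angle scattering (SAXS/SANS) analysis of
core–shell nanoparticles in R, built around the formulation problem posed
by lipid nanocapsules (LNCs): a triglyceride oil core inside a thin,
heavily hydrated PEGylated surfactant shell. A single scattering curve
cannot resolve such a shell; measuring the same particles under several
solvent/core isotopic contrasts (h-/d-core in H2O/D2O) and fitting all
curves **simultaneously** with one structural model can. The package is
aimed at scattering practitioners and formulation scientists who want that
workflow scripted, testable and reproducible.

## What it computes

* **Composition → SLD**: neutron/X-ray scattering length densities from
  chemical formulas (deuterium-aware Hill parser, bundled bound coherent
  scattering-length table), H2O/D2O solvent series, contrast match points,
  and shell hydration from a fitted shell SLD via linear mixing
  `rho_shell = (1-h) rho_dry + h rho_solvent`.
* **Forward model**: absolute-scale polydisperse core–shell sphere
  intensity
  `I(Q) = 1e-4 (phi/<V_t>) <F^2(Q)> S(Q) + b` (cm^-1, Å units, SLDs on
  the 1e-6 Å^-2 scale), `F = V_t Δρ_shell Φ(QR_t) + V_c Δρ_core Φ(QR_c)`,
  with Gaussian core-radius polydispersity and an optional Percus–Yevick
  hard-sphere structure factor.
* **Resolution**: per-point Gaussian Q smearing of model curves.
* **Real-space analysis**: Guinier fits and a regularized indirect Fourier
  transform (Moore sine basis + second-derivative penalty) giving p(r),
  Rg, I(0) and a Dmax scan.
* **Simultaneous multi-contrast fitting**: shared structural parameters
  (core radius, shell thickness, polydispersity, hydration, volume
  fraction) across datasets with fixed computed SLDs, profiled per-dataset
  backgrounds/scales, bounded Levenberg–Marquardt with seeded multi-starts,
  covariance-based uncertainties, and derived quantities (total radius,
  per-contrast shell SLD, hydration %, theoretical volume fraction).
* **Synthetic data**: seeded generators for the four-contrast SANS design,
  SAXS sets, a core-matched scenario and a dilution series, so the whole
  pipeline runs without any external data.

## Worked example

Simulate the four-contrast SANS series of unloaded LNCs at 3% noise and
fit it:

```r
library(sascontrast)

solvent_sld(0); solvent_sld(1)      # H2O -0.56, D2O 6.37 (1e-6 A^-2)
lnc_core_sld("h"); lnc_core_sld("d") # oil core 0.15, 5% d-oil blend 0.43

scenario <- lnc_scenarios(noise_pct = 3, seed = 207)$unloaded
datasets <- simulate_scenario(scenario)   # h/d-core x H2O/D2O, 120 pts each
problem  <- build_problem(datasets)       # fixed SLDs from contrast labels
fit      <- sas_fit(problem, seed = 7)
print(fit)
```

```
<fit result> chi2_red = 1.04 over 480 points (seed 7)
  core_radius              201.32 +- 1.17
  shell_thickness          12.502 +- 3.15
  polydispersity          0.20129 +- 0.00351
  hydration                0.5156 +- 0.142
  volume_fraction        0.008852 +- 0.000393
  ...
  total radius: 213.82 +- 2.94 A; hydration: 51.6%
```

The generating truth was core radius 200 Å, shell 15 Å, polydispersity
0.20, hydration 0.50, volume fraction 0.009: every parameter is recovered
within its 1σ–2σ interval, and χ²_red ≈ 1 confirms the noise model. The
derived shell SLD in D2O, `(1-h)*0.13 + h*6.37 = 3.35`, is the number such
studies quote as "the fitted shell SLD", and
`hydration_from_sld(3.35, 0.13, 6.37)` inverts it back to the hydration.
A hydration of ~50% means half the shell volume is solvent — the
signature of a brush-like PEG corona rather than a compact layer.

A thin command-line wrapper over the same functions ships in
`inst/cli/sas_tool.R` (`sld`, `simulate`, `pr`, `fit`, `report`
subcommands).

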