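---
title: "Contrast-variation small-angle scattering analysis of core–shell nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-variation small-angle scattering analysis of core–shell nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sascontrast)
```

## The problem

Lipid nanocapsules (LNCs) are drug-delivery nanoparticles with a
triglyceride oil core stabilised by a PEGylated surfactant shell
(Kolliphor HS 15 plus a small phospholipid fraction). Their overall size is
easy to measure, but the internal core–shell architecture — core radius,
shell thickness, and how much water the PEG shell carries — is only
accessible to small-angle X-ray and neutron scattering (SAXS/SANS).
Because the shell is thin and heavily hydrated, a single scattering curve
cannot pin it down. The classical remedy is *contrast variation*: the same
particles are measured with a hydrogenous or partially deuterated oil core,
dispersed in H2O or D2O, and all curves are fitted *simultaneously* with
one structural model in which only the scattering length densities (SLDs)
differ between datasets. `sascontrast` implements that whole pipeline:

* composition → SLD arithmetic (neutron and X-ray), solvent contrast
  series, match points, and hydration inference;
* the absolute-scale polydisperse core–shell sphere forward model with an
  optional Percus–Yevick hard-sphere structure factor;
* Gaussian Q-resolution smearing;
* Guinier analysis and a regularized indirect Fourier transform (IFT) for
  the pair-distance distribution p(r);
* simultaneous multi-contrast fitting with fixed computed SLDs and a shared
  hydration parameter;
* a synthetic-data generator that emulates the four-contrast SANS design
  plus point-collimation SAXS, so every stage is testable end to end.

## SLDs from composition

The neutron SLD of a molecule is $\rho = \sum_i b_i / V_m$ with $b_i$ the
bound coherent scattering lengths and $V_m = M/(\rho_m N_A)$ the molecular
volume from molar mass and mass density; the X-ray SLD replaces
$\sum b_i$ with $Z_{tot}\, r_e$ ($r_e = 2.818\times10^{-5}$ Å). The
scattering-length table is bundled so results do not drift with external
databases. All SLDs are reported on the $10^{-6}\,\text{Å}^{-2}$ scale.

```{r}
sld("H2O", "neutron", density = 0.997)   # light water
sld("D2O", "neutron", density = 1.107)   # heavy water
sld("H2O", "xray", density = 0.997)
```

Densities are configurable with defaults chosen to reproduce the standard
tabulated SLDs of the formulation components within 2%: water 0.997, heavy
water 1.107, Labrafac 0.94 (0.93–0.95 plausible), Kolliphor HS 15 1.0
g/cm³. Kolliphor is represented by its ethylene-glycol repeat C20H40O4, the
convention used by formulation SLD tables, not the full PEG-15 molecule.
One caveat worth knowing: the widely quoted Kolliphor pair (0.13 neutron /
9.92 X-ray) is not attainable from C20H40O4 at any single density — the
ratio $\sum b_i/(Z r_e)$ fixes their proportion at a different value — so
the package treats those as tabulated reference constants
(`dry_shell_sld()`) and keeps the fully computed route (`sld()` on the
`lnc_materials()` component) available. Fits and generators use the same
constant, so the analysis is self-consistent either way.

The deuterated-core blend (95% Labrafac + 5% octanoic-d15/decanoic-d19
acids by mass) is combined by mass→volume-fraction conversion at component
densities; the deuterated acid densities are the protiated values scaled by
the isotopic mass ratio. This yields 0.43, slightly below the commonly
quoted 0.45 for this blend — the quoted value is not recoverable from the
stated composition under any reasonable density, and the package uses its
computed value throughout.

Hydration inference inverts linear volume-fraction mixing,
$h = (\rho_{shell}^{fit} - \rho_{dry})/(\rho_{solv} - \rho_{dry})$, and is
the exact inverse of `mix_sld()`; implied hydrations outside $[-0.05,
1.05]$ raise an error (inconsistent SLDs), small excursions are clipped.

## The forward model

For core radius $R_c$, shell thickness $t$ ($R_t = R_c + t$):

$$ I(Q) = 10^{-4}\,\frac{\phi}{\langle V_t\rangle}\,\langle F^2(Q)\rangle\,S(Q) + b, \qquad
F(Q) = V_t(\rho_{sh}-\rho_{solv})\,\Phi(QR_t) + V_c(\rho_c-\rho_{sh})\,\Phi(QR_c) $$

with $\Phi(x) = 3(\sin x - x\cos x)/x^3$, lengths in Å, SLDs numerically on
the $10^{-6}\,\text{Å}^{-2}$ scale and $I$ in cm⁻¹; the $10^{-4}$ factor is
the Å→cm unit conversion under that SLD scaling (the convention of standard
SAS modelling software). The number density is always derived as
$\phi/\langle V_t\rangle$, never a free parameter.

Polydispersity is a Gaussian *number* distribution of the core radius
(σ/mean is the reported polydispersity), truncated at ±3σ (and zero),
with fixed shell thickness, averaged as $\langle F^2\rangle/\langle
V_t\rangle$ by Gauss–Legendre quadrature (35 nodes by default, ≥15
enforced; 35 nodes agree with a 10⁵-sample Monte-Carlo average to better
than 0.5%). This matches the convention of mainstream fitting software so
a fitted volume fraction keeps its meaning.

$S(Q) = 1$ by default — the SANS measurements this design targets are at
$\phi \lesssim 0.01$ where the exact Percus–Yevick $|S-1|$ bound,
$1-(1-\phi)^4/(1+2\phi)^2 \approx 7\%$ at $Q\to 0$ and under 1% beyond
$Q = 0.05$ Å⁻¹, justifies the choice. The PY factor can be switched on
(`hs_structure = TRUE`) with $r_{eff}$ the mean total radius, e.g. for
concentrated SAXS samples; both modes are available because the
appropriate treatment at 62 mg/mL is genuinely ambiguous.

## Resolution smearing

Reduced pinhole-SANS data carry a per-point Gaussian σ_Q; model curves are
convolved in Q over each point's ±3σ window (Gauss–Legendre, default 31
nodes — 21 is the accuracy floor but misses the 0.2% agreement with a
2001-node brute-force convolution on sharp monodisperse curves, so the
default is higher). Windows crossing $Q \le 0$ are truncated and
renormalized. The SANS default is δQ/Q = 0.08 constant (a typical
time-of-flight pinhole figure; the true instrument function is not
recoverable from reduced data), SAXS point collimation is unsmeared; both
are per-dataset overridable, and a 4th data-file column is read as σ_Q.

## Guinier and p(r) analysis

`guinier_fit()` fits ln I vs Q² over an iteratively selected window
$Q R_g \le 1.3$. A $Q^4$ curvature term is included by default because the
pure two-term fit carries a systematic +1.6% window bias for spheres at
this cutoff; with the correction the sphere $R_g = \sqrt{3/5}\,R$ is
reproduced to 0.1% on noise-free curves.

`ift()` expands p(r) in a Moore sine series on $[0, D_{max}]$ (boundary
conditions automatic) and solves the Tikhonov-regularized weighted least
squares problem with the second-derivative penalty $\alpha\int p''^2$,
which is diagonal in this basis. α is specified relative to the data-misfit
curvature ($\alpha_{abs} = \alpha\,\mathrm{tr}(A^TWA)/\mathrm{tr}(P)$,
default $10^{-2}$); the default number of terms is the Shannon number
$\lfloor Q_{max} D_{max}/\pi\rfloor$ clamped to [8, 64]. `scan_dmax()`
selects the smallest support whose reduced χ² is within 5% of the scan
minimum and whose negative lobes stay under 5% of the peak — a
deterministic, testable stand-in for evidence-based selection; a scan in
which no candidate is admissible (or the best χ²_red exceeds 3) is flagged
non-ideal. Reported $D_{max}$ is the selected support length, and reported
uncertainties are fit-covariance based.

## Simultaneous contrast fitting

The key modelling decision: the shell SLD is *never* fitted directly.
One shared hydration fraction $h$ gives every dataset its shell SLD by
mixing, $\rho_{sh,j} = (1-h)\rho_{dry} + h\rho_{solv,j}$ — the only way a
single physical shell can be consistent across H2O and D2O datasets. The
published single "fitted shell SLD" of such analyses is recovered as the
derived D2O-contrast value. Core and solvent SLDs are fixed at their
computed values. Shared structural parameters: core radius, shell
thickness, polydispersity, hydration, volume fraction (default bounds
50–600 Å, 0–100 Å, 0–0.6, 0–1, 10⁻⁴–0.3). Per-dataset scale (fixed at 1
by default — absolute-scale data) and background (free) are *linear*
parameters and are profiled out of the nonlinear search by weighted least
squares (variable projection), which roughly halves the optimizer
dimension.

The optimizer is bounded Levenberg–Marquardt with multi-starts: a
deterministic data-driven guess (Guinier radius and forward-intensity
volume fraction of the highest-contrast dataset, gridded over hydration
{0.25, 0.5, 0.75} because the hydration axis has basins of attraction at
its bounds) plus 5 seeded Latin-hypercube points; the two best distinct
cheap candidates are polished to tight tolerances and the lower final χ²
wins, ties broken toward the smaller core radius. Everything is
deterministic given the seed. Uncertainties come from the Gauss–Newton
covariance at the optimum over the *full* parameter vector; the total
radius error uses the full covariance including the core–shell
off-diagonal term. Parameters within numerical tolerance of a bound are
flagged.

`parameter_covariance()` evaluates the same covariance at user-chosen
parameter values without optimizing — the clean way to study information
content. A core-contrast-matched measurement of this formulation is the
instructive case: because the dry shell SLD nearly equals the core SLD, a
core-matched solvent extinguishes the shell too, and the Fisher
information for the core radius collapses by orders of magnitude relative
to the four-contrast design. (An optimizer run on such essentially
signal-free data lands in noise-fitting minima with meaninglessly sharp
curvature, which is why the information statement is made at the true
parameters.)

Single-contrast fits (e.g. a dilution series measured only in D2O) cannot
resolve hydration from shell thickness and volume fraction — freeing all
five parameters drives hydration and thickness into bound-riding
degeneracies. The supported design is to fix hydration at the value from
the multi-contrast analysis and fit the remaining four, which is what the
battery examples and tests do.

## The synthetic-data generator

`lnc_scenarios()` bundles the study conditions: an "unloaded" 4-contrast
SANS series (core radius 200 Å, shell 15 Å, polydispersity 0.20, hydration
0.50, volume fraction 0.009), its drug-"loaded" counterpart (202 Å, 20 Å,
0.25, 0.70, 0.009), single-contrast SAXS sets at 62 mg/mL (φ = 0.092;
217 Å/26 Å/0.20 and 185 Å/36 Å/0.35), a core-matched scenario, and a
1.24/3.1/6.2 mg/mL dilution triple with φ scaling proportionally. The
unloaded shell, published only as a "≤1.5 nm" bound, is generated at
1.5 nm. SANS grids are 120 log-spaced points over 0.003–0.7 Å⁻¹ with
δQ/Q = 0.08; SAXS grids are 200 points over 0.0076–3 Å⁻¹ unsmeared.
Backgrounds are 0.8 cm⁻¹ in H2O and 0.06 cm⁻¹ in D2O (typical incoherent
levels) and 0.02 cm⁻¹ for SAXS.

Noise is multiplicative Gaussian — σ = (noise%/100)·I plus a floor of
10⁻⁴·I(Q_min) — a counting-statistics proxy appropriate to reduced data
that carry Gaussian error bars; the recorded σ column is the true noise
scale (verified by a Kolmogorov–Smirnov test on z-scores in the test
suite). At zero noise the dataset equals the smeared model exactly and the
σ column keeps the floor so weighted fits stay defined. Real reduced data
differ in ways the generator does not emulate — Q-dependent counting
noise, residual incoherent backgrounds that are not flat, imperfect
absolute calibration, and inter-particle interference beyond PY — so
passing round-trip tests demonstrates correctness of the estimator under
its own assumptions, not robustness to every instrumental artefact. Noise
levels of 1–5% are realistic for such measurements; 3% is the default
study condition.

## Numerical choices, sizes and limitations

* Sphere kernel: series below $x = 10^{-3}$; PY structure factor: series
  below $2QR = 0.05$ with the exact $Q=0$ compressibility limit.
* Quadratures: 35-node polydispersity, 31-node smearing, 513-point
  trapezoid for the IFT design matrix, 256-point p(r) grid.
* Optimizer: stage-1 LM capped at 80 iterations per start, polish at
  ftol 10⁻¹⁴; χ²_red on noise-free self-generated data reaches machine
  precision.
* Test problem sizes: 120-point 4-contrast fits; ensembles of 20 seeds for
  the recovery suite (a full fit takes a few seconds on one CPU).
* Limitations: spherical one-shell models only; no slit smearing; no
  Bayesian IFT or posterior sampling; temperature/salt scenario variations
  are replicate seeds of one truth (structure assumed stable), no
  temperature physics; incoherent/absorption cross-sections and anomalous
  X-ray dispersion are out of scope.
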