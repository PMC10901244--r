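---
title: "Layered modified Beer-Lambert reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered modified Beer-Lambert reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(layernirs)
```

## The problem

Continuous-wave fNIRS measures, at two or more near-infrared wavelengths,
the attenuation of light that has diffused through scalp, skull,
cerebrospinal fluid (CSF) and cortex between a source and a detector a few
centimetres apart on the head surface. The quantity of scientific interest
is the pair of concentration changes Δ[HbO], Δ[HbR] of oxy- and
deoxyhemoglobin in the *cortex*; the dominant nuisance is the hemodynamics
of the *scalp*, which the light crosses twice. The standard homogeneous
analysis — the modified Beer-Lambert law (MBLL) with a scalar differential
pathlength factor (DPF) — attributes all absorption change to a single
compartment and is well known to underestimate cortical changes and to
inherit scalp artifacts ("inverse response"). This package implements and
evaluates the alternative: treat the head as a stack of optically
homogeneous planar layers, compute each layer's **mean partial pathlength**
(MPPL) analytically from the diffusion equation, and invert the
two-wavelength, two-distance MBLL system for scalp (role U) and gray-matter
(role L) changes jointly.

## Forward model

Light transport is modelled by the continuous-wave diffusion approximation,
$(-D\nabla^2 + \mu_a)\Phi = S$ with $D = 1/(3\mu_s')$ per layer. For a
semi-infinite N-layered medium the fluence is expanded over the roots
$\alpha_n$ of $J_0$ in a cylinder of radius $R' = R + z_b$ (a finite Hankel
transform); for each transverse eigenvalue $s_n = \alpha_n/R'$ the
remaining two-point problem in depth is solved by a downward admittance
recursion through the stack, coupling layers by continuity of fluence and
normal flux. The recursion is written in `tanh` form so it remains finite
for arbitrarily large $s$ — a requirement, since several thousand terms are
summed.

Boundary and source model:

* isotropic point source at depth $z_0 = 1/\mu_{s,1}'$;
* extrapolated boundary at $z = -z_b$, $z_b = 2 D_1 (1+R_{\rm eff})/(1-R_{\rm eff})$,
  with $R_{\rm eff}$ from angular integrals of the unpolarised Fresnel
  reflectance ($R_{\rm eff} = 0.431$ for tissue $n = 1.33$ against air);
* the detected signal is the outward flux at the surface (Fick's law).
  We also implemented the radiance-based hybrid detector
  ($0.132\,\Phi + 0.336\,J$ at $n=1.33$) and compared both against a
  photon-transport Monte Carlo reference; the flux detector was uniformly
  closer, so it is the package's detector model.

In the homogeneous limit the expansion collapses analytically to the
familiar two-image-source closed form, which the package exposes as
`semi_infinite_reflectance()`; the layered solver matches it to better than
0.1% for separations of 5-40 mm (in practice to ~1e-8 relative), and both
match an independent adaptive quadrature of the continuous Hankel
representation.

### Tunable solver parameters

| parameter | default | meaning |
|---|---|---|
| `cylinder_radius` | 150 mm | lateral truncation of the expansion; must well exceed the largest separation. Truncation error decays like $e^{-\mu_{\rm eff}(2R-\rho)}$ and is negligible at the default. |
| `max_terms` | 4000 | Bessel-root budget. The series tail decays like $e^{-s z_0}$ *relative to the prefactor*; strongly absorbed geometries (small total reflectance) need more terms, and the solver raises an explicit convergence error rather than returning a truncated sum. |
| `tol` | 1e-8 | relative tail tolerance: the largest term of a trailing 500-term block must fall below `tol` times the partial sum. |
| `rel_step` | 1e-4 | relative central-difference step for MPPLs (absolute floor 1e-6 mm⁻¹). A step-halving check in the test suite confirms first-order Richardson agreement. |

### Mean partial pathlengths

$L_j(\lambda,\rho) = \partial A/\partial \mu_{a,j}$ with $A = -\ln(I/I_0)$,
evaluated at the baseline optical properties by central finite differences
on the layered forward solution. Natural logarithms are used throughout
(so $L_j$ is in mm), and extinction coefficients are stored in natural-log
basis — decadic literature values times $\ln 10$. The MPPLs obey two exact
identities used as tests: their sum equals the derivative of $-\ln R$ under
a simultaneous perturbation of every layer (sum rule), and each $L_j \ge 0$.
Collapsing an internal layer's thickness to zero removes its pathlength and
reproduces the (N-1)-layer solution.

## Chromophores

The bundled extinction table holds compiled in-vivo hemoglobin spectra at
690 and 830 nm (decadic 276/2051.96 and 974/693.04 cm⁻¹M⁻¹ for HbO/HbR),
one wavelength on each side of the isosbestic point near 800 nm. Baselines
quoted at the isosbestic wavelength are converted to concentrations by
solving the 2x2 extinction system with the same absorption on both rows
(`mua_to_conc`); concentrations map back to per-wavelength absorption by
the linear Beer-Lambert relation (`conc_to_mua`). With this table and the
ln-basis convention, a scalp baseline of 0.018 mm⁻¹ gives
(58.78, 30.19) µM and the gray-matter baseline 0.036 mm⁻¹ gives
(117.56, 60.38) µM; the mua-conc round trip is exact to machine precision.
The table is data, swappable via a three-column text file with a declared
basis.

## The activation simulator

Two block protocols bracket realistic combinations of scalp and cortical
activity (five blocks each):

* **Situation 1** (48 s blocks): scalp and cortex activate simultaneously
  at 8 s for 8 s — scalp +10% HbO, -5% HbR; cortex +50% HbO, -25% HbR.
* **Situation 2** (50 s blocks): scalp -25% HbO from 6 s for 8 s (HbR
  constant); cortex +50% HbO, -25% HbR from 10 s for 12 s. Time-shifted,
  opposite HbO signs.

Each fractional-change boxcar is convolved per block with a canonical
double-gamma hemodynamic response (peak 6 s, undershoot 16 s, dispersions
1 s, undershoot ratio 1/6, kernel length 32 s) and normalised to its own
peak, so the peak concentration equals baseline x (1 + nominal change)
exactly; blocks are then tiled. Sampling is 10 Hz by default. These
choices, made once, are the package's reading of "canonical": the peak
normalisation pins the printed peak concentrations, while the waveform
shape is only qualitatively constrained. Under these defaults the Pearson
correlation between the two proposed ΔHbO time courses in Situation 2 is
-0.36; we note it is sensitive to the HRF parameterisation (across
canonical variants we observed -0.27 to -0.43, and -0.27 for the raw
boxcars), so analyses that depend on this number should treat it as
shape-dependent.

Attenuation data are generated per channel (a long and a short separation)
at both wavelengths in two modes:

* **nonlinear** — the layered forward model is re-solved at every
  timepoint with the scalp and gray-matter absorptions implied by the
  concentration series (other layers fixed); $A = -\ln(I/I_0)$ then
  carries the full nonlinear dependence. This is the honest data
  generator.
* **linear** — $A = L_U\,\Delta\mu_{a,U} + L_L\,\Delta\mu_{a,L}$ with
  baseline MPPLs; by construction the layered inversion recovers the
  inputs exactly (an "inverse crime"), which is used to validate the
  linear-algebra path to 1e-9 µM.

Optional multiplicative Gaussian intensity noise (seeded) is available but
off by default; the reference analyses use noiseless data. The generator
emulates planar layered geometry only: no curved anatomy, no partial-volume
activation, no physiological nuisance (cardiac, respiration, Mayer waves)
and no motion artifacts — so passing tests validate the solver and
inversion algebra, not robustness to those real-data features.

## The Monte Carlo reference

`mc_slab()` is an independent photon-transport simulation for two-layer
media: an isotropic-scattering (reduced) random walk with exponential free
paths in $\mu_s'$, continuous absorption weighting $e^{-\mu_a l}$, Russian
roulette below weight 1e-4, an unpolarised-Fresnel top boundary, and
per-layer pathlength tallies of photons escaping into 1 mm annuli. It makes
no use of the diffusion approximation and is the package's accuracy
reference. At 1e6 photons (the unit-test size) Monte Carlo noise dominates
and solver and reference agree within 3 standard errors at 10, 20 and
30 mm; at 1e7 photons (the acceptance-size run at 30 mm) the standard
errors shrink to ~0.5% and the residual transport-vs-diffusion systematic
(~1-2% on the scalp pathlength at mid distances) becomes resolvable — a
known, documented limit of the diffusion approximation at these albedos,
not a solver defect.

## Reconstruction methods

All three methods act on the same attenuation series through
`reconstruct_hb()`:

* **layered** — per timepoint, the 4x4 system linking
  $A(\lambda_i,\rho_k)$ to (ΔHbO, ΔHbR) in roles U and L through
  $\varepsilon_X(\lambda_i) L_j(\lambda_i,\rho_k)$ is solved by SVD
  pseudo-inverse (singular values below 1e-12 of the largest are dropped;
  the condition number of the untruncated system is reported and fits
  above 1e10 are flagged rather than erroring). MPPLs are computed once at
  baseline and held fixed. The five-layer head and the two-layer merge
  (scalp + semi-infinite remainder with gray-matter properties; a
  thickness-weighted alternative is provided) are both supported.
* **homogeneous** — the DPF approximation, $\Delta = E^{-1}A/({\rm DPF}\,\rho)$
  with DPF = 6.
* **short_corrected** — the long channel is first regressed against its
  short channel with the plain inner-product ratio
  $K = \langle A_s, A_l\rangle/\langle A_s, A_s\rangle$ per wavelength
  (mean-centering available as an option), then inverted homogeneously.
  When long and short channels are proportional this yields exactly flat
  output — which is what happens for temporally correlated layer dynamics,
  and is the documented failure mode of the correction.

On nonlinear five-layer data the layered inversion recovers the cortical
peaks within ~10% (the 25% acceptance band is comfortably met); the
homogeneous method underestimates them by an order of magnitude, and on
Situation 2 its ΔHbO takes the scalp's negative sign during the scalp-only
window — the inverse response.

## Prior sensitivity

`prior_sensitivity()` sweeps symmetric relative grids around the assumed
baseline absorptions (±50%) or the scalp/gray-matter thicknesses (±25%) of
the two active layers, rebuilding the MPPL matrix and re-running the
layered inversion at each node, and records the RMSE
$\sqrt{n^{-1}\sum_i(\Delta[{\rm HbX}]_{i,\rm retr}-\Delta[{\rm HbX}]_{i,\rm prop})^2}$
per role and species. With exact (linear-mode, noiseless) data the minimum
of every surface sits at the true priors — the package's correctness check —
while on nonlinear data the surfaces quantify how forgiving the inversion
is to wrong priors. Solver failures at a node yield an `NA` entry rather
than aborting the sweep. Grid resolution is a free parameter (21x21 is a
reasonable production choice; the tests use 3x3).

## Problem sizes used by the test-suite

Chosen so the full suite runs in a few minutes on one CPU while keeping
every check in a regime where it is informative: protocol and chromophore
checks at the full 10 Hz; nonlinear end-to-end reconstructions at 2 Hz
(peaks are insensitive to sampling); inverse-crime and sensitivity-grid
checks at 1 Hz, one block, 3x3 grids; Monte Carlo cross-checks at 1e6
photons in the unit tests and one 1e7-photon run at 30 mm in the
acceptance tests.

## Known limitations

* Planar layers; no curvature, no lateral inhomogeneity of the activation.
* The diffusion approximation is assumed valid in every layer, including
  CSF (given diffusion-compatible optical properties by construction).
* Two active roles only (scalp, gray matter); the general N-role system is
  documented but not exposed.
* The DPF=6 homogeneous method and the K-factor correction are implemented
  as comparison baselines, faithfully including their failure modes.
* The reported MPPLs are exact only as far as the diffusion approximation:
  against photon transport expect ~1-2% systematic deviations at 20-30 mm
  separations for head-like optical properties.
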