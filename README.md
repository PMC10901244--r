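# layernirs

Layered-model reconstruction of hemoglobin concentration changes for
continuous-wave functional near-infrared spectroscopy (CW-fNIRS).

## The problem

CW-fNIRS infers changes in oxy- and deoxyhemoglobin (Δ[HbO], Δ[HbR]) in
the cortex from light attenuation measured on the scalp at two wavelengths
straddling the hemoglobin isosbestic point (~800 nm). The standard
analysis treats the head as a homogeneous medium via the modified
Beer–Lambert law (MBLL) with a differential pathlength factor (DPF),

&nbsp;&nbsp;&nbsp;&nbsp;A(λ, ρ) = [ε<sub>HbO</sub>(λ) Δ[HbO] + ε<sub>HbR</sub>(λ) Δ[HbR]] · DPF · ρ,

which cannot separate scalp from cortical hemodynamics: it underestimates
cortical changes and can flip their sign when the scalp is active (the
"inverse response"). The layered alternative implemented here writes the
natural-log attenuation of an N-layered medium as

&nbsp;&nbsp;&nbsp;&nbsp;A(λ, ρ) = Σ<sub>j</sub> L<sub>j</sub>(λ, ρ) Δμ<sub>a,j</sub>(λ),&nbsp;&nbsp;&nbsp;
Δμ<sub>a,j</sub>(λ) = ε<sub>HbO</sub>(λ) Δ[HbO]<sub>j</sub> + ε<sub>HbR</sub>(λ) Δ[HbR]<sub>j</sub>,

where L<sub>j</sub> = ∂A/∂μ<sub>a,j</sub> is the **mean partial
pathlength** (MPPL) of detected photons in layer j. With two wavelengths
(690/830 nm) and two source–detector separations (a short, scalp-dominated
channel and a long channel), the 4×4 system is solved per timepoint by SVD
for the changes in the scalp (U) and gray-matter (L) compartments jointly.

The package provides:

* a CW diffusion forward solver for semi-infinite N-layered media
  (finite Hankel expansion over Bessel roots; extrapolated boundary;
  flux detector) and analytical MPPLs as absorption derivatives;
* hemoglobin extinction tables and isosbestic baseline conversions;
* a block-design activation simulator (two reference "situations",
  canonical double-gamma HRF) and a forward data generator (full
  nonlinear re-solve or linearised MBLL);
* three reconstruction methods behind one fitting function
  (`reconstruct_hb()`): layered SVD inversion (2- or 5-layer head),
  homogeneous DPF, and short-separation-corrected homogeneous (Saager
  K-factor regression);
* a photon-transport Monte Carlo reference for two-layer slabs (Rcpp);
* RMSE-based prior-sensitivity grids over baseline absorptions (±50%)
  and layer thicknesses (±25%);
* a YAML-configured pipeline (`run_pipeline()`) with a thin Rscript CLI
  (`inst/cli/layernirs.R`).

## Worked example

Five-layer adult head model (scalp, skull, CSF, gray matter, white
matter), channel with a 31.3 mm long and 8.3 mm short separation:

```r
library(layernirs)
hm <- head_model()
mppl(hm, rho = 31.3)
#>        SC         SK        CSF         GM         WM
#> 219.131999  29.815770  18.593090   4.398480   1.521616
```

At the long separation a detected photon spends on average 219 mm in the
scalp but only 4.4 mm in the gray matter — the core quantitative reason
scalp signals dominate raw fNIRS channels.

Simulate the simultaneous scalp+cortex activation protocol (scalp +10%
HbO / −5% HbR, cortex +50% HbO / −25% HbR) with full nonlinear forward
data, then invert:

```r
cs  <- concentration_timeseries(situation_protocol(1, sample_rate = 2))
att <- forward_attenuation(cs, hm, probe_layout(), mode = "nonlinear")
fit <- reconstruct_hb(att, "layered", medium = hm)
fit
#> Hemoglobin reconstruction (layered), channel 1, 480 timepoints
#>   4x4 system condition number: 592
#>     dhbo_U     dhbo_L     dhbr_U     dhbr_L
#>   5.824317  52.880481  -1.504789 -14.621001
```

The true proposed peaks are +5.88 / +58.78 µM (HbO, scalp/cortex) and
−1.51 / −15.10 µM (HbR): the layered inversion recovers the cortical HbO
peak within 10% and the scalp peaks within 1%. The homogeneous DPF method
on the same data gives

```r
coef(reconstruct_hb(att, "homogeneous"))
#>      dhbo      dhbr
#>  8.034547 -2.098283
```

— an order-of-magnitude underestimate of the cortical change, because it
spreads the absorption change over the whole DPF·ρ pathlength.

`plot(fit, truth = cs)` overlays retrieved and proposed time courses;
`summary()`, `coef()`, `fitted()` and `residuals()` behave as for other R
model objects. See the methods vignette
(`vignettes/layered-mbll-methods.Rmd`) for the model, parameter and
design-choice documentation.

## Command line

```sh
Rscript inst/cli/layernirs.R simulate    --config inst/extdata/example_config.yaml --out out/
Rscript inst/cli/layernirs.R mppl        --out out/
Rscript inst/cli/layernirs.R reconstruct --out out/
Rscript inst/cli/layernirs.R evaluate    --out out/ --grid-steps 5
```

Artifacts are deterministic for a fixed config and seed, carry the config
hash, and are written as tidy CSV plus JSON sidecars.

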