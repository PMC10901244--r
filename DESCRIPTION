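Package: layernirs
Title: Layered-Model Reconstruction of Hemoglobin Changes for CW-fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and reconstruction of oxy- and
    deoxyhemoglobin concentration changes from continuous-wave functional
    near-infrared spectroscopy (CW-fNIRS) attenuation data. Implements a
    continuous-wave diffusion-equation solver for semi-infinite N-layered
    head models (finite Hankel expansion over Bessel roots), analytical
    per-layer mean partial pathlengths obtained as absorption derivatives
    of log-reflectance, modified Beer-Lambert inversions (homogeneous
    differential-pathlength-factor method, short-separation channel
    regression, and a layered singular-value-decomposition inversion), a
    block-design activation-protocol simulator with canonical hemodynamic
    response convolution, a photon-transport Monte Carlo oracle for
    two-layer slabs, and prior-sensitivity analyses over baseline
    absorption and layer thicknesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
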