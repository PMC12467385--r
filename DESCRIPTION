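Package: pulsepinn
Title: Physics-Informed Inference of Pulmonary Artery Pressure from
    Sparse Area and Velocity Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the blood pressure field in the main pulmonary artery
    bifurcation from sparse, image-derived time series of cross-sectional
    area and axial velocity. Couples a reduced-order (1D) Navier-Stokes
    blood-flow model with one small neural network per vessel, trained
    with physics, data, and bifurcation-interface penalty terms so that
    the inferred fields satisfy mass conservation, momentum balance, an
    elastic pressure-area constitutive law, and flow and total-pressure
    continuity at the junction. Also provides the image-derived wall
    mechanics chain (Lagrange smoothing of velocity waveforms, Gaussian
    pulse fitting, cross-correlation pulse-wave-velocity estimation,
    Young's modulus and the stiffness parameter beta), and a
    Lax-Wendroff reference solver that generates ground-truth bifurcation
    hemodynamics and clinical-like boundary measurements for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
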