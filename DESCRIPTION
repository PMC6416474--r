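Package: photodose
Title: Monte Carlo Light Transport and Singlet-Oxygen Dosimetry for
    Photodynamic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-based Monte Carlo simulation of light fluence rate in
    turbid tissue coupled to macroscopic photokinetic rate equations for
    type II photodynamic therapy (PDT). Computes three-dimensional maps of
    reacted singlet oxygen concentration ([1O2]rx, the singlet-oxygen
    dose) for collimated disc illumination of a voxelized target volume,
    supports homogeneous and simple heterogeneous optical phantoms, fits
    the one-dimensional analytic fluence-ratio model used to cross-check
    Monte Carlo depth profiles, and provides the tumor-regrowth cure-index
    and logistic dose-response analysis that links simulated singlet
    oxygen dose to treatment outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
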