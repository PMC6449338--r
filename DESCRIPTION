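Package: permflux
Title: Membrane Permeability from Umbrella Sampling via the
    Inhomogeneous Solubility-Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate membrane permeability of small solutes from
    umbrella-sampling window time series. Reconstructs the potential of
    mean force along the membrane normal by the weighted histogram
    analysis method (WHAM) with histogram-level bootstrap errors,
    estimates the position-dependent diffusion coefficient from the
    autocorrelation of force fluctuations with block-averaged errors,
    and combines both into the local resistance profile, total
    resistance and permeability of the inhomogeneous
    solubility-diffusion model with first-order error propagation.
    Includes a one-dimensional overdamped Langevin generator with
    position-dependent diffusivity that provides analytically known
    ground truth for end-to-end parameter-recovery tests, a spherical-cell
    conversion between first-order uptake kinetics and permeability, and
    structural observables of bilayers (density profiles, head-group peak
    positions, acyl-chain order parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
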