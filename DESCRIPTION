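Package: daemfit
Title: Multi-Distribution Activation Energy Models for Thermogravimetric
    Pyrolysis Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic analysis of slow biomass pyrolysis measured by
    simultaneous thermogravimetry and differential scanning calorimetry
    (TGA/DSC). Implements the first-order distributed activation energy model
    (DAEM) with Gaussian, Logistic, Gumbel and Cauchy activation-energy
    distributions; forward simulation of conversion-rate (DTG) curves for
    pseudo-component mixtures; preprocessing of raw thermograms
    (Savitzky-Golay smoothing, conversion normalization, numerical
    differentiation, replicate averaging); bounded nonlinear least-squares
    estimation of pseudo-component parameters with peak-based initialization
    and component-count/distribution-family scans; and heuristics that
    rationalize the pseudo-component count by concordance between DTG peaks
    and heat-flow (DSC) events. A synthetic-data generator produces
    TGA/DSC-like thermograms with controlled kinetics, enthalpy signs and
    instrument noise so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
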