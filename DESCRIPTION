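Package: wirespec
Title: Vibrational Dynamics and Nonlinear Spectroscopy of Nanoconfined Water Wires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    quasi-one-dimensional water chains in cylindrical confinement.  Reads
    extended-XYZ trajectories with velocities, computes axial diffusion from
    mean-square displacements, orientational correlation functions,
    vibrational densities of states, instantaneous OH-stretch frequencies by
    continuous Morlet wavelet transform, frequency distributions and the
    intramolecular donor/free asymmetry, joint frequency distributions,
    frequency-frequency time-correlation functions, two-level-system
    third-order response functions, 2D-IR correlation spectra, integrated
    three-pulse photon-echo intensities and their short-time slope, and
    hydrogen-bond statistics with continuous lifetime correlation.  Includes
    a minimal flexible-water force-field generator for confined water wires
    and exact stochastic-process generators (Ornstein-Uhlenbeck frequencies,
    axial Brownian motion, rotational diffusion) used as analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
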