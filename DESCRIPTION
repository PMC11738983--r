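Package: trapkin
Title: Single-Molecule Binding Kinetics from Nanoaperture Optical Trap Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of label-free single-molecule binding experiments
    recorded as optical transmission time series through a nanoaperture
    optical trap. Provides a telegraph-signal simulator with
    state-dependent Gaussian noise, zero-phase low-pass conditioning and
    segmentation of raw traces, two-state Gaussian-emission hidden Markov
    state inference with restarts and a dwell-duration spurious-transition
    correction, single-exponential residence-time CDF fitting, and
    ligand-depletion-corrected rate constants (kon, koff, KD, standard
    Gibbs energy) via the mass-balance quadratic. Companion ensemble-assay
    fitters cover one-site fluorescence-polarization titrations, thermal
    melt Tm extraction from the 350/330 nm fluorescence ratio, and
    two-point CPMG transverse relaxation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
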