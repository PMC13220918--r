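Package: fliphasor
Title: Phasor and Decay-Fit Analysis of Fluorescence Lifetime Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of time-resolved fluorescence lifetime imaging (FLIM)
    photon-count cubes: phasor computation with single or per-pixel instrument
    response function (IRF) calibration, universal-circle lifetime mapping,
    automatic reference finding by intersecting the principal axis of inertia
    of a phasor cloud with the universal circle, two-component linear phasor
    decomposition into amplitude-averaged lifetime maps, and single- or
    double-exponential iterative-reconvolution decay fitting by weighted or
    unweighted nonlinear least squares or Poisson maximum likelihood.
    Includes region-of-interest tools (label masks, intensity thresholds,
    grids), dataset conditioning (binning, background and pile-up correction),
    parameter maps with multi-peak Gaussian histogram fits, a ground-truthed
    synthetic scene generator, HDF5/TIFF/CSV/JSON input and output, and a
    scriptable end-to-end workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
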