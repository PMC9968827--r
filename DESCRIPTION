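Package: columnEEG
Title: Forward Modeling of Scalp EEG from Laminar Cortical Column Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a mesoscopic forward-modeling chain that links laminar
    field-potential recordings from a cortical column to scalp EEG topographies.
    The package simulates populations of reduced layer-3 and layer-5 pyramidal
    cells driven by noisy current pulses, computes extracellular potentials at a
    linear electrode array under the point-source approximation, estimates
    volumetric current source density by the standard second-derivative method
    and by the spline inverse CSD (iCSD) method, converts CSD profiles or summed
    transmembrane currents into equivalent current dipoles with cortical-normal
    orientations, and solves the EEG forward problem for nested
    piecewise-homogeneous head models with a boundary element method validated
    against an analytic concentric-sphere solution. Agreement between forward
    solutions is quantified with the relative difference measure (RDM) and the
    magnitude ratio (MAG), and multi-dipole source configurations can be
    enumerated and ranked against empirical scalp topographies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
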