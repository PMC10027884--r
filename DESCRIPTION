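Package: arcdose
Title: Volumetric Dose Reconstruction from Rotational Ion-Chamber-Array Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for studying how linear
    interpolation reconstructs volumetric radiotherapy doses from planar
    ion-chamber-array measurements acquired during rotational (VMAT)
    delivery. Provides detector-array lattice models (Octavius 729/1500,
    MatriXX), cylindrical-coordinate geometry, an analytic arc-beam
    ground-truth dose generator with percent-depth-dose tables and
    mass-density phantoms, per-control-point planar measurement simulation
    with noise and low-dose-rate dropout, unilinear/bilinear/angular
    interpolation and percent-depth-dose extension into a volumetric dose,
    dose-volume-histogram metrics, and scripted experiments quantifying how
    detector spacing, tissue heterogeneity, spatial sampling, and structure
    volume govern the accuracy of reconstructed DVH metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
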