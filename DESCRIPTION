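Package: stormfoci
Title: Coordinate-Based Analysis of Two-Color Single-Molecule Localization
    Microscopy Data at DNA Damage Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing d-STORM / SMLM localization tables of
    nuclear protein assemblies: Thompson localization precision and quality
    filtering, blinking-event merging across consecutive frames, fiducial
    channel registration, Voronoi-volume and neighbor-count denoising,
    Delaunay-graph cluster segmentation with graph-diameter extension
    measurements, helical-filament geometry conversion, two-color
    colocalization metrics (centroid, point-to-point and end-to-point
    distances), bivariate Ripley's K with Monte-Carlo randomization
    envelopes, robust multi-group max-t statistics, and a ground-truth
    synthetic scene simulator for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    FNN,
    igraph,
    jsonlite,
    sp,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy, used for 3D Voronoi
    tessellation volumes.
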