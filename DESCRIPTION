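Package: rootqsm
Title: Quantitative Structure Models of Coarse Root Systems from Terrestrial Laser Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cylinder-based quantitative structure models (QSMs) of
    excavated coarse-root systems from terrestrial laser scanning point clouds.
    Covers the cloud with bounded-diameter surface patches, segments the taproot
    and lateral roots by patch-graph expansion, fits cylinders selected by a
    surface-coverage statistic, assigns centrifugal root orders, and extracts
    architectural traits (length, volume, number) by order, cardinal quadrant
    and depth. Includes the PatchDiam calibration procedure (grid sweep, linear
    interpolation, intersection with digitized reference traits, brute-force
    refinement and a 20-model ensemble), a reader for flat MTG-style digitized
    reference records with frustum-based trait computation, and a procedural
    root-system generator with a simulated three-viewpoint laser scanner for
    fully synthetic validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
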