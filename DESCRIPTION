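Package: nbaxis
Title: Division-Axis Quantification for Neuroblast Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for 3D division-axis maintenance in
    Drosophila larval neuroblasts imaged by anisotropic time-lapse
    fluorescence microscopy. Provides exact inter-axis angle geometry in
    physical coordinates, telophase shape-based and centrosome-based
    division-axis extraction, neuroblast/glia surface-contact morphometry by
    isosurface triangulation, EdU proliferation volume quantification, exact
    Mann-Whitney U condition comparisons, and a synthetic 4D scene generator
    with known ground truth so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    xml2,
    e1071,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
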