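Package: objlayer
Title: Object-Based Image Analysis with Label Maps, Voronoi Neighbourhoods
    and Processing Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Object-based analysis of 2-D microscopy images: images are
    segmented into labelled objects (a label map plus per-object contour,
    class and feature records), topological relationships between objects
    are derived by discrete Voronoi tessellation of the label map, and
    analyses are composed from named, argument-bearing processing steps
    serialized as JSON chains. Includes H-DAB color deconvolution for
    immunohistochemistry scoring (Ki67 positive-fraction counting),
    class-relational features (shared border length, neighbouring and
    touching object counts), CSV results export, and seeded synthetic-image
    generators with exact ground truth for bright-field IHC and
    three-channel fluorescence (osteoclast-bone contact) scenes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
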