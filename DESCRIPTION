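Package: chronotrap
Title: Time-Lapse Sticky-Trap Image Analysis and Insect Chronoecology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn time-lapse images of adhesive insect traps into
    chronoecological statistics. Provides tiled instance detection with
    cross-tile Jaccard deduplication and size filtering, appearance-based
    pairwise matching (naive and delayed self-similarity plus geometric
    features through a small decision head), three-pass graph tracking into
    multi-frame insect "tuboids" (contiguous linking, gap bridging, conjoint
    merging), multi-frame taxonomic classification by element-wise median
    feature fusion, and circadian analysis: Warped Zeitgeber time, low-pass
    capture-rate filtering, lag-24 h autocorrelation rhythmicity tests, diel
    activity profiles, bootstrap multidimensional scaling of temporal niches,
    diel-window capture fractions, and trap-saturation linearity tests. A
    synthetic scene simulator (inhomogeneous Poisson arrivals with diel
    intensity, rendered blob series with jitter, occlusion and escape)
    supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    xml2,
    nnet,
    vegan,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    jpeg
Config/testthat/edition: 3
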