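Package: chinassay
Title: Automated Quantification of Chemically Induced Inflammation in
    Zebrafish Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies leukocyte infiltration of lateral-line neuromasts in
    well-plate fluorescence images of zebrafish larvae (the chemically
    induced inflammation, or ChIn, assay). From three-channel z-stacks
    (bright-field, GFP-labelled neuromasts, DsRED2-labelled leukocytes) the
    pipeline selects the central focal plane, builds a five-slice extended
    focus projection, detects neuromasts as green blobs, measures the mean
    relative red fluorescence in a square region around each neuromast, and
    aggregates per-larva scores into per-condition summaries compared with
    Welch's unpaired t-tests. A count mode reproduces manual scoring of
    leukocyte spots within a band around the horizontal myoseptum. A
    synthetic plate generator with known ground truth makes every stage
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
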