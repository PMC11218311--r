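Package: periplaque
Title: Peri-Plaque Microglial Barrier, Neurite Dystrophy, Sholl and
    Plasma miRNA Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification toolkit for amyloid-plaque
    neuropathology and a plasma miRNA screen, exercised on synthetic
    data with known ground truth. Segments amyloid plaques from
    multi-channel fluorescence stacks, measures microglial (Iba1)
    coverage of the plaque perimeter as the fraction of 1-degree
    arcs colocalized with Iba1, extends covered and uncovered
    angular sectors to the limit of the Lamp1-positive halo to
    quantify dystrophic-neurite area per angular degree, counts
    plaque-associated microglial somata within a fixed physical
    radius, performs Sholl analysis of neuron morphologies from SWC
    files or binary masks, scores FITC-amyloid phagocytosis per
    segmented cell, and implements an miRNA count screen with
    expression filtering, trimmed-mean-of-M-values normalization, a
    negative-binomial exact-style test, Benjamini-Hochberg FDR,
    a 95 percent confidence-interval signature rule, PCA scores and
    2^-ddCt relative expression. A synthetic-data module generates
    calibrated image stacks, morphologies and count matrices with
    ground-truth tables for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
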