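Package: nanocluster
Title: Spatial Statistics and FLIM-FRET Analysis of Membrane Protein
    Nanoclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies nanoscale clustering of plasma-membrane proteins
    from immunogold electron-microscopy point patterns: the edge-corrected
    univariate Ripley K-function and its variance-stabilised L(r)-r
    transform, Monte-Carlo complete-spatial-randomness envelopes, and
    bootstrap comparison of replicated patterns between experimental
    conditions. Also provides frequency-domain FLIM lifetime estimation
    with reference-standard calibration and apparent FRET efficiency,
    deterministic phenotype scoring rules (neurite outgrowth, tumorsphere
    counting, densitometry ratios), and synthetic-data generators
    (binomial CSR, Thomas cluster process, immunogold labeling noise,
    FLIM phase/modulation frames) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    spatstat.explore,
    spatstat.geom,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
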