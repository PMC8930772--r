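Package: ldscope
Title: Lipid Droplet Phenotyping from Yeast Micrographs via Spatial-Embedding Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying lipid droplet (LD)
    phenotypes in budding yeast micrographs. Cells are segmented in
    brightfield images by a convolutional network that predicts per-pixel
    spatial embeddings, a seed map and a clustering bandwidth; instances are
    recovered by iterative seed clustering, filtered, and exported as convex
    hull ROIs. Per-cell LD numbers are obtained from the BODIPY fluorescence
    channel by particle counting over a descending intensity-threshold sweep
    with a maximum rule, and supersized droplets are scored by a thresholded
    area criterion. Strain comparisons use a blocked (experiment-linked)
    one-way ANOVA with step-down Sidak adjusted pairwise tests. A synthetic
    scene generator with exact ground truth makes every stage testable
    without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
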