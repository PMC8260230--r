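Package: streakdyn
Title: Quantitative Analysis of Primitive Streak Cell Dynamics and Clonal
    Lineage Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify cell behaviour in the gastrulating amniote
    embryo around the primitive streak: kinematic analysis of nuclear
    time-lapse tracks (node registration, convergence angles and speeds,
    track longevity, ingression-intensity gradients, inter-division times),
    clone identification from retroviral barcodes and from multispectral
    (Brainbow-type) nuclear color codes via k-means clustering with a
    silhouette quality filter and ternary-plot coordinates, a geometric-series
    model of progenitor population growth under partial ingression with
    forward projection and parameter recovery, percentile-threshold image
    quantification of double-positive nuclei and mitotic indices, and a
    sliding-window statistic for dynamically variable genes along a
    pseudotime ordering. Includes synthetic-data generators with known
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
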