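Package: vcellseg
Title: Unsupervised Tissue-Compartment Segmentation of H&E Histology by
    Virtual Cells and Consensus Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments brightfield images of haematoxylin-and-eosin stained
    tissue into epithelium and stroma without any training data. Colour
    deconvolution separates the stain channels; mathematical morphology
    (h-concave nuclear seeds, opening by reconstruction, marker-controlled
    watershed) partitions the stained tissue into "virtual cells", one per
    detected nucleus; 63 colour and shape descriptors are measured per
    virtual cell; a 31-member cluster ensemble (k-means, unsupervised LVQ,
    EM, density-based reassignment, agglomerative hierarchical) is pruned to
    moderate diversity by the average Rand index and combined by evidence
    accumulation or Jaccard-aligned majority voting. Includes evaluation
    against pixel-level gold standards and a synthetic H&E image generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    mclust,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
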