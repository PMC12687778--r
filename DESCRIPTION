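Package: salnet
Title: Saliency Correlation Networks from Volumetric Severity Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of structural MRI severity spectra with
    residual convolutional classifiers and gradient saliency. Generates
    synthetic T1-weighted cohorts with planted regional effects, trains 2D
    and 3D residual networks (softmax, tanh and sigmoid heads, and hybrid
    feature-vector variants classified by k-nearest-neighbours or a support
    vector machine), extracts voxel saliency maps, aggregates them over a
    two-hemisphere atlas parcellation, and derives Kendall tau saliency
    correlation networks, hub rankings, functional-network involvement
    summaries, phenotype-score correlation tables, hemisphere asymmetry
    statistics and control-group congruence measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    class,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
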