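Package: clustbench
Title: Evaluation of Unsupervised Subtype Discovery in Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking unsupervised cancer-subtype discovery in
    high-dimensional gene expression data. Provides a factor-model simulator
    for log-scale expression cohorts with subtype, sex and age effects;
    pre-processing filters for constant and lowly expressed genes; variable
    selection (top-N standard deviation) and feature extraction (principal
    components); six clustering methods (Ward hierarchical clustering with
    Manhattan or absolute-correlation distance, k-means, a self-organizing
    map, affinity propagation, and a hard Euclidean least-squares consensus
    ensemble); partition-agreement measures (adjusted Rand index, average
    pairwise ARI, variation of information); and subsampling experiment
    designs probing sample size, subtype proportion, and sex heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
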