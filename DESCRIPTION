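Package: rnnclust
Title: Random Neural Network Cluster Classification of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/control classification of functional brain connectomes with a
    random neural network cluster: graph-theoretic feature extraction (degree,
    clustering coefficient, shortest path length, local efficiency) from ROI
    time series, an ensemble of randomly subsampled neural network base
    classifiers (backpropagation, probabilistic, competitive, learning vector
    quantization and Elman networks) combined by majority voting, and a
    feature-frequency procedure that ranks discriminative features and maps
    them to brain-region importance weights. Includes a synthetic cohort
    generator with planted connectivity differences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
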