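Package: netdcm
Title: Network Discovery for fMRI with Dynamic Causal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of directed, cyclic effective-connectivity networks
    from regional BOLD time series. Simulates resting-state-like data from a
    linear stochastic neuronal network driving a balloon hemodynamic model,
    inverts a fully connected dynamic causal model by variational Laplace to
    a Gaussian posterior over coupling parameters, scores every sparsity
    structure (adjacency matrix) of the network with a Savage-Dickey
    log-evidence proxy, and characterises the selected graph by spectral
    embedding of the weighted graph Laplacian and a hierarchy ordering
    derived from connection asymmetries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
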