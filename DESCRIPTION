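Package: triomics
Title: Semi-Supervised Weighted Joint Non-Negative Matrix Tri-Factorization for Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates several non-negative omics matrices measured on a shared
    set of samples by jointly tri-factorizing each matrix X ~ U S V around a
    common sample factor V. Partial sample labels enter through an
    affinity/penalty graph-Laplacian regularizer built from a side feature
    matrix, per-omic weights on the probability simplex are learned by a
    closed-form quadratic program so that noisier matrices contribute less,
    and unlabeled samples are classified from their latent factor loadings.
    Fitted molecular factors are turned into connected multi-omics modules by
    z-score feature selection, projection onto an interaction network, and
    hypergeometric gene-set enrichment. Includes consensus-clustering rank
    selection and a planted-truth synthetic data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
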