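Package: lmflnc
Title: Metabolite-Disease Interaction Prediction via Logistic Matrix
    Factorization with Local Neighborhood Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts metabolite-disease interactions by logistic matrix
    factorization regularized with local spectral (Vicus) matrices built
    from metabolite and disease similarity networks.  Includes construction
    of disease semantic similarity from a term hierarchy (Lin's
    information-content measure), metabolite functional similarity from
    gene annotations, weighted K-nearest-known-neighbor smoothing of the
    sparse interaction matrix, cold-start projection of latent vectors for
    nodes without observed interactions, cross-validated evaluation
    (AUPR/AUC/F1), and a synthetic-data generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
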