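Package: lsme
Title: Locality-Sensitive Multi-Embeddings for Edit Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns (d1,d2)-locality-sensitive multi-embedding functions for
    the edit distance on fixed-length DNA sequences: each sequence is mapped
    to k Euclidean vectors by an inception-style convolutional encoder trained
    with a Siamese contrastive hinge loss, so that sequences within edit
    distance d1 are within a margin delta in at least one embedding component
    while sequences at edit distance d2 or more are farther than delta in all
    components. Includes a seeded pair simulator with boundary-distance
    training-set assembly, per-distance accuracy evaluation and parameter
    sweeps, exact-reference indexed neighbour search (radius and KNN) with
    repetition-union TP/FP curve accounting, classical baselines (random-order
    minimizer seeding, the CGK edit-to-Hamming embedding, bit-sampling Hamming
    LSH), and a synthetic cell-barcode whitelist application.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
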