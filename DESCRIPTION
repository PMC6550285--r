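Package: codetag
Title: Multilabel Diagnosis-Code Tagging for Clinical Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains and evaluates a bidirectional recurrent multilabel
    tagger that assigns top-level diagnosis codes to free-text clinical
    notes. Includes hierarchical label-similarity training objectives (a
    cluster penalty on label embeddings and a noisy-OR meta-disease loss),
    a learned abstention wrapper with retention-curve evaluation, a full
    multilabel evaluation protocol (per-code precision/recall/F1/AUC,
    exact-match ratio, weighted and unweighted aggregates, and a
    performance-heterogeneity regression), and a synthetic corpus
    generator that emulates keyword-driven multilabel notes, subtype
    diversity, long-tailed code frequencies, and cross-hospital domain
    shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
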