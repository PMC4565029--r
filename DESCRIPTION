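Package: licornr
Title: Cooperative Transcription Factor Network Inference from Expression
    Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers large-scale cooperative transcription factor (TF)
    networks from gene expression matrices with a hybrid
    discrete-continuous search (h-Licorn): ternary discretization of
    expression, level-wise frequent-itemset mining of co-regulator sets,
    truth-table scoring of candidate regulatory programs and linear
    re-scoring by ordinary least squares.  Networks can be refined with
    external regulatory and co-regulatory evidence, summarized into
    sample-specific TF influence statistics computed from signed target
    sets, and condensed into a co-regulation network by hypergeometric
    testing of shared targets with false-discovery-rate control.  A
    synthetic benchmark generator with precision-recall scoring makes
    every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
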