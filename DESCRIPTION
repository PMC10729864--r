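Package: coregnet
Title: Gene Co-Regulation Networks from Heterogeneous Differential
    Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene pairs that are differentially expressed
    together across many small heterogeneous two-group contrasts. Differential
    expression calls are tabulated in a binary genes-by-contrasts matrix; the
    significance of each pair's co-regulation count is assessed against a
    beta-binomial null fitted to fixed-margin (curveball) resamplings of that
    matrix. Significant pairs are scored for non-linear (mixed-direction)
    concordance, screened for Simpson's-paradox geometry, and assembled into a
    scale-free co-regulation network with recursive Louvain module detection
    and an annotation interaction-density validation against random networks.
    A synthetic-data generator with planted ground truth supports benchmarking
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
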