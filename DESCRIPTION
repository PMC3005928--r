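Package: homolarray
Title: Cross-Species Homology Search Microarray Design, Simulation and
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Design cross-species microarray probes from transcript sets by
    capped infix (semi-global) edit-distance screening with a q-gram
    prefilter, simulate two-sample hybridization experiments with
    edit-distance-dependent signal decay, multiplicative noise and a 20-bit
    scanner ceiling, and analyse intensity tables: background-based
    detection calls, homolog candidates at a high-expression intensity
    threshold, known/new homolog classification, fold-change lists between
    two tissues and three-set Venn summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
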