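Package: dynregnet
Title: Dynamic Transcriptional Regulatory Networks from Time-Course
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers dynamic transcriptional regulatory networks from
    replicated time-course expression experiments. Implements network
    component analysis (NCA), a constrained bilinear decomposition of a
    log-ratio expression matrix into transcription-factor activities and
    control strengths under a known connectivity zero-pattern, together
    with the surrounding pipeline: empirical-Bayes moderated-t selection
    of differentially expressed genes, correlation-based augmentation of
    the connectivity prior, identifiability checking and pruning,
    post-fit activity analytics, hypergeometric pathway enrichment, and a
    permutation test for pathway crosstalk on a weighted protein-protein
    interaction network. A synthetic-data generator produces every input
    with the statistical structure the analysis assumes, so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
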