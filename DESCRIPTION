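Package: txduality
Title: Activation, Repression and Nonmonotonicity in Models of
    Transcriptional Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Graph-based (linear framework) models of how a transcription
    factor regulates a target gene: steady states of molecular state
    graphs by equilibrium path products and by spanning-tree (Matrix-Tree)
    summation, the four-state regulated-recruitment model with its
    closed-form equilibrium response and direction condition, TF-regulated
    transcription-cycle models, and multisite occupancy models with
    saturable rate modulation. Provides fold-change response curves,
    monotonicity classification, regime maps over affinity, concentration
    and binding-site number, and a synthetic massively parallel reporter
    assay (MPRA) simulator with shape-constrained AIC trend analysis,
    for studying when a single transcription factor acts as an activator,
    a repressor, or both.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
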