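Package: uexpress
Title: Uncertainty-Propagating Expression Summarisation, Differential
    Expression and Clustering for Microarray Probe Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probe-level gamma models for expression summarisation with
    measurement uncertainty (a multi-mapping-aware model for exon-array
    probes and a PM-only model for 3' GeneChip probe-sets), differential
    expression scoring by the probability of positive log-ratio under a
    hierarchical Bayesian replicate model solved by a fully analytic
    variational EM, and robust Student's-t mixture clustering of replicated
    expression profiles that propagates per-value measurement error, with
    automatic selection of the number of clusters by minimum message
    length. Includes seeded generators that simulate data from each model
    with known ground truth, plain-text (TSV) interchange formats, and
    global-scaling normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
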