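Package: margcausal
Title: Marginal Causal Inference for Gene Networks from Knock-Out
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes downstream-causally related to a single
    knocked-out gene from replicated observational (wild-type) and
    interventional (knock-out) expression data. For each candidate gene a
    downstream Gaussian structural-equation model is compared against a
    pooled upstream/correlated alternative via a Bayes factor computed
    from maximized Gaussian likelihoods, and the total causal effect of
    the knocked-out gene is estimated by maximum likelihood. Includes a
    Gaussian structural-equation simulator on weighted directed acyclic
    graphs with single-node do-interventions, an exact total-effect
    oracle, a self-contained moderated t-test baseline, and a benchmark
    harness (ROC/AUC, F-score) for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    jsonlite
Config/testthat/edition: 3
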