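Package: consensusDEG
Title: Method-Agnostic Consensus Reference Standards for Single-Subject
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs method-agnostic reference standards for evaluating
    differential gene expression calls in single-subject (one RNA-seq sample
    per condition, no replicates) designs. Candidate gene universes are
    defined by a grid of low-expression cutoffs and symmetric fold-change
    windows; the grid is searched for the first parameter combination at
    which the median pairwise Jaccard concordance between independent
    differential-expression callers reaches a user target. Consensus
    positives (intersection or strict majority vote) over the remaining
    callers, with the evaluated method excluded to avoid isomorphic
    evaluation bias, form the reference standard against which hold-out
    single-subject sample pairs are scored by precision and recall. Includes
    four built-in two-condition callers spanning exact conditional,
    negative-binomial Wald, rank-based and delta-method z-test families, an
    adapter for externally computed DEG tables, and a negative-binomial
    count simulator with planted fold changes for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
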