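Package: plastisig
Title: Embryonic Plasticity Gene Signatures and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives embryonic-stage "plasticity" gene expression signatures
    from a staged expression atlas by moderated two-group differential
    expression (empirical-Bayes variance shrinkage with closed-form moment
    matching), maps mouse signatures to human genes through Homologene-format
    tables, computes single-sample plasticity scores (highest-variance probe
    collapsing, per-gene z-normalization, +/-1 weighted averaging), and
    stratifies patient cohorts by score for Kaplan-Meier / log-rank survival
    analysis with a time-to-10%-events group comparison. A synthetic-data
    module simulates every input -- staged atlases with planted gene programs,
    homology tables, proportional-hazards patient cohorts, and cell-line
    panels -- with recorded ground truth, so the full pipeline runs with no
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
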