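Package: seqruleged
Title: Sequential Rule Mining for Longitudinal Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rule-based, interpretable mining of time-lagged gene-gene
    relations from longitudinal expression studies with multiple subjects.
    Expression changes per time interval are discretized into up/down/no-change
    events by comparing each subject's signal log ratio against the group mean,
    per-group sequence databases are built in the SPMF text format, and
    sequential rules (LHS before RHS) are mined with a two-phase algorithm:
    an Apriori pass over flattened sequences followed by sequential
    cut-point counting. Each rule carries five frequentist quality metrics
    (sequential support and confidence, lift, certainty factor, conviction)
    and five biological quality measures computed from gene-set annotations
    (GO-style namespaces, pathways) and a transcription-factor/target table.
    Includes very-strong-rule filtering, group-contrast mining, cross-cohort
    rule replication matching, a circular bundled-edge network plot, a
    synthetic-data generator with planted rules for validation, and a
    command-line pipeline driver.
License: GPL-3
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
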