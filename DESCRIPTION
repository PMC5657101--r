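Package: savant
Title: Sample-Level Scoring and Visualization of Molecular Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates ranked molecular signatures from multi-sample
    expression compendia via proportional-median (PM) values, scores
    signature collections across individual samples of an expression
    matrix, attaches permutation-based empirical p-values and group-wise
    one-way ANOVA, and renders clustered heatmaps of the
    signature-sample matrix. Supports GMT gene sets, ranked signature
    tables, and tab-delimited expression matrices with an embedded
    group-label row, plus a synthetic-data generator with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
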