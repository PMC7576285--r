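Package: immrisk
Title: Immune-Related lncRNA Co-Expression Networks and Immune-Risk
    Stratification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies tumour-specific immune-cell-population marker genes
    and long non-coding RNAs (lncRNAs) from tumour versus normal expression
    profiles, screens gene-lncRNA pairs whose Pearson correlation changes
    between the two conditions, builds per-population bipartite differential
    co-expression networks with degree and power-law analysis, scores each
    patient by rank-based risk features to stratify the cohort into three
    immune-risk groups, and compares the groups by Kaplan-Meier and log-rank
    survival analysis.  A synthetic-data generator with planted ground truth
    supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
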