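Package: fosnet
Title: Functional Connectomics of Regional c-Fos Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyzes correlation-based functional brain networks from
    per-animal regional immediate-early-gene (c-Fos) cell counts. Provides baseline
    normalization against a homecage group, per-region between-condition activation
    tests with an engagement-classification rule, per-condition Pearson correlation
    matrices with Fisher-Z edge comparisons and anatomical-group connectivity
    summaries, p-value-thresholded functional networks with graph summary measures,
    community detection with within-community degree z-scores, participation
    coefficients and provincial/connector hub classification, four-measure centrality
    ranking with top-quartile hub identification, and a group-label permutation test
    for between-network centrality differences. Includes a synthetic cohort generator
    with block-structured correlation and planted activation effects so the whole
    pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
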