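Package: rankenrich
Title: Dual-Contrast Rank-Based Gene Set Enrichment for RNA-seq
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end pipeline for testing whether gene sets respond in a
    coordinated way across one or two differential-expression contrasts.
    Provides low-count filtering, log-CPM normalization, a moderated two-group
    t-test with empirical-Bayes variance shrinkage, a signed significance score
    for ranking genes, classic-mode pre-ranked gene set enrichment analysis
    (KS-style running sum with a gene-tag permutation null), a two-dimensional
    rank MANOVA test of joint gene-set displacement across two contrasts with
    Benjamini-Hochberg FDR control, qPCR relative-quantification arithmetic
    (comparative Ct and ChIP percent-input), and a negative-binomial count
    simulator with planted coordinated effects for validating the whole chain.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
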