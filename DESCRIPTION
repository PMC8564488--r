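Package: consensig
Title: Cross-Study Consensus Gene Signatures for Dendritic Cell Phenotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives consensus gene-expression signatures across multiple
    small transcriptomic studies of a cell phenotype (tolerogenic, alternatively
    activated and mature dendritic cells are the motivating use case). Each
    study is quantile- or TMM-normalized and analysed individually with an
    empirical-Bayes moderated t-statistic; per-study statistics are converted
    to directional z-scores and combined across studies with Pearson's method
    of p-value combination into an overall significance score, from which a
    thresholded up/down gene signature is derived. Downstream tools provide
    rank-based pathway enrichment (Wilcoxon rank-sum on combined p-values and
    preranked GSEA), directional validation of a signature on held-out studies,
    and projection of signatures onto single-cell expression via bin-matched
    module scores. A synthetic multi-study data generator with known ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
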