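Package: lncnet
Title: LncRNA Discovery and lncRNA-miRNA-mRNA Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("lncnet", "maintainers", email = "lncnet@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline from transcript models and expression
    counts to a tripartite lncRNA-miRNA-mRNA regulatory network, built for
    two-condition plant RNA-seq designs (bulk strand-specific RNA-seq plus
    small RNA-seq). Implements long noncoding RNA identification (expression,
    length, same-strand exonic overlap and open-reading-frame filters) with
    positional classification (lincRNA, antisense, sense, overlapping);
    negative-binomial differential expression with median-of-ratios
    normalization and a moderated Wald test; cis (100 kb window plus
    co-expression) and trans (genome-wide co-expression) target assignment;
    plant miRNA target prediction with expectation-scored duplex alignment;
    endogenous target mimic (eTM) calling under seed, mismatch-budget and
    central-bulge rules; miRNA precursor identification by local alignment
    identity; hypergeometric term enrichment; and network assembly. A
    synthetic-data module generates a fully specified toy study with planted,
    machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
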