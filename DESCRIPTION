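Package: nadcapr
Title: Mapping and Quantifying Non-Canonical RNA Caps from Circularization
    and Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two complementary analyses of NAD-capped RNA in
    budding yeast. The first maps non-canonical cap-addition sites at
    nucleotide precision from circularized-RNA (circNC) amplicon reads:
    read-pair merging, polyA-run filtering, semi-global junction alignment,
    cap-site and 3'-end calling, and classification of cap sites as
    adenosine-templated or post-transcriptionally added. The second
    classifies NAD-capped transcripts from capture versus standard RNA-seq
    count matrices with a negative-binomial enrichment test,
    Benjamini-Hochberg adjustment, and the twofold / q <= 0.01 decision
    rule, together with permutation and hypergeometric statistics for
    gene-set overlaps. A synthetic-data module generates transcriptomes,
    junction amplicon reads with ground truth, and count matrices with
    planted enrichment so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
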