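Package: cernaforge
Title: ceRNA Network Inference for Oxidative and Glycolytic Muscle
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained downstream pipeline for lncRNA and circRNA
    regulatory analysis of two-group bulk RNA-seq count data, modelled on
    oxidative (sartorius) versus glycolytic (pectoralis major) chicken
    muscle. Provides FPKM/CPM normalization, a two-group negative-binomial
    exact test with the p < 0.05 and |log2 fold change| >= 1 filter,
    structural lncRNA and circRNA candidate filters, 10 kb cis-target
    assignment, hypergeometric over-representation analysis, canonical
    miRNA seed matching, and competing-endogenous-RNA (ceRNA) triad
    inference combining Spearman/Pearson correlation filters with a
    hypergeometric shared-sponge test. Ships a seeded synthetic-data
    generator that plants differential expression, cis placements and
    ceRNA triads so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
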