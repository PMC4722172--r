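Package: coexkit
Title: Construction and Assessment of Mutual-Rank Gene Coexpression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds Mutual Rank (MR) gene coexpression tables from RNA-seq
    count matrices (filtering, log transformation, per-experiment quantile
    normalization, Pearson correlation, rank conversion), compares coexpressed
    gene lists within and between species with the COXSIM prefix-concordance
    statistic and its empirical-null significance, derives reciprocal-best-hit
    orthology from Blastp bitscore tables, scores whole coexpression datasets
    (GO score, codon score, reproducibility score), clusters datasets and
    classifies lineage-specific coexpression of ortholog pairs, and draws
    coexpression networks with subnetwork detection and GO / promoter-heptamer
    enrichment. A seeded synthetic-fixture generator with planted ground truth
    produces every input the toolkit consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    limma,
    Biostrings,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
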