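Package: editome
Title: Detection, Classification and Comparative Analysis of RNA Editing
    Sites from Matched DNA/RNA Pileups
Version: 0.1.0
Authors@R:
    person("Editome", "Maintainers", email = "maintainers@editome.example",
           role = c("aut", "cre"))
Description: Detects RNA editing sites by point-by-point comparison of
    matched genomic DNA and RNA per-site base counts, applies a
    coverage/support/frequency filter cascade with known-variant masking
    and cohort-level filters, resolves A-to-I and C-to-U editing classes
    on unstranded libraries via gene-annotation strand collapse, and
    characterizes sites functionally (nonsynonymous recoding, flanking
    base preference, clustering, exon-boundary proximity). Provides
    tissue-specific, population-specific and population-differential
    editing-site callers (Wilcoxon rank-sum with Benjamini-Hochberg
    adjustment), editing-level versus gene-expression correlation, and a
    seeded synthetic-data generator that emulates a two-population,
    four-tissue study design with planted SNPs and editing sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
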