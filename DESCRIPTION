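Package: vmscreen
Title: Screening Retrotransposons for Inter-Individual Methylation Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying variably methylated LTR retrotransposons
    (metastable epialleles) from whole-genome bisulphite sequencing data.
    Repairs fragmented RepeatMasker annotations of IAP-class endogenous
    retroviruses (500 kb boundary patching, structure classification and a
    gap-bounded mending heuristic), screens element edges for inter-individual
    methylation range per cell type with coverage-based informativeness
    filters, and discovers k-mer derived sequences enriched in variably
    methylated LTRs (presence counting, fold enrichment, k-1 overlap
    assembly and enrichment-maximising trimming). Includes a seeded synthetic
    data generator that emulates the study design, so every stage can be
    exercised against known truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
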