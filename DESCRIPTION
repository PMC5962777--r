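Package: florvar
Title: Clade-Specific Variant Discrimination for Flor Yeast Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested pipeline, a comparative-genomics analysis
    for identifying genetic variants specific to flor (sherry) yeast strains of
    Saccharomyces cerevisiae relative to wine strains: a two-clade read-frequency
    discrimination filter over multi-sample variant calls, variant effect
    classification against gene models with a count-based dN/dS ratio, gene-level
    polymorphism stratification with hypergeometric enrichment, breadth-of-coverage
    gene presence/absence and non-reference gene detection, and a neighbor-joining
    phylogeny from a SNP major-allele matrix. Ships a truth-annotated synthetic
    clade-structured data generator so every stage is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
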