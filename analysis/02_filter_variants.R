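#!/usr/bin/env Rscript
# Stage 2: the clade discrimination filter (20x depth, 90% read frequency,
# biallelic) and the locus count. Writes results/calls.tsv.

suppressMessages(library(florvar))

groups <- read_groups("results/sim/groups.tsv", in_clade = "flor")
vs <- read_variants("results/sim/calls.vcf", groups)
calls <- call_clade_specific(vs, groups, filter_thresholds())
write_clade_calls(calls, "results/calls.tsv")

genes <- read_gene_models("results/sim/genes.gff3")
genome <- read_genome("results/sim/genome.fa")
loci <- summarize_loci(calls, genes, genome)

truth <- read.table("results/sim/truth_sites.tsv", sep = "\t",
                    col.names = c("chrom", "pos", "ref", "alt", "type",
                                  "clade_allele", "category"))
planted <- truth$pos[truth$type == "clade_specific"]
message(sprintf("%d/%d sites pass the filter; planted set recovered: %s",
                nrow(calls), nrow(vs$sites), setequal(calls$pos, planted)))
message(sprintf("calls fall in %d distinct genomic loci", loci$n_loci))
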