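#!/usr/bin/env Rscript
# Stage 6: SNP-matrix site selection (0.9 major-allele frequency, 20x depth,
# invariant sites excluded), concatenation, p-distances and the NJ tree.
# Writes results/snp_alignment.fa and results/tree.nwk.

suppressMessages(library(florvar))

groups <- read_groups("results/sim/groups.tsv")
vs <- read_variants("results/sim/calls.vcf", groups)
m <- select_tree_sites(vs, min_freq = 0.9, min_depth = 20)
message(sprintf("%d sites retained for the SNP alignment", nrow(m$alleles)))
seqs <- concatenate_snp_matrix(m, "results/snp_alignment.fa")
tree <- neighbor_joining(p_distance(m))
write_newick(tree, "results/tree.nwk")
flor <- grep("^flor", m$samples, value = TRUE)
message(sprintf("flor samples monophyletic: %s",
                is_clade_monophyletic(tree, flor)))
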