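#!/usr/bin/env Rscript
# Stage 1: generate the clade-structured synthetic dataset (truth-annotated).
# Writes results/sim/: genome, annotation, multi-sample VCF, coverage, hit
# tables, group file and truth tables.

suppressMessages(library(florvar))

cfg <- sim_config(seed = 20180515)   # all downstream stages reuse this run
sim <- generate_dataset(cfg, "results/sim")

message(sprintf("genome: %d bp, %d genes (%d with introns)",
                cfg$genome_length, length(sim$genes),
                sum(vapply(sim$genes, function(g) nrow(g$introns) > 0, logical(1)))))
message(sprintf("samples: %d flor / %d wine", cfg$n_clade_a_samples,
                cfg$n_clade_b_samples))
print(table(sim$truth$sites$type))
message(sprintf("planted deletions: %s",
                paste(unique(sim$truth$deleted_genes$gene_id), collapse = ", ")))
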