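#!/usr/bin/env Rscript
# Stage 3: effect classification of the clade-specific calls, the category
# table and the count-based dN/dS ratio. Writes results/effects.tsv and
# results/category_table.tsv.

suppressMessages(library(florvar))

groups <- read_groups("results/sim/groups.tsv")
vs <- read_variants("results/sim/calls.vcf", groups)
calls <- call_clade_specific(vs, groups)
genes <- read_gene_models("results/sim/genes.gff3")
genome <- read_genome("results/sim/genome.fa")

effects <- annotate_calls(calls, genes, genome)
tab <- tabulate_categories(effects)
write_report(list(effects = effects,
                  category_table = data.frame(category = names(unclass(tab)),
                                              count = as.integer(tab))),
             "results")
print(tab)
message(sprintf("dN/dS (missense/synonymous count ratio) = %.2f", dn_ds(tab)))
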