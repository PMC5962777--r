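#!/usr/bin/env Rscript
# Stage 5: breadth-of-coverage gene presence/absence (<50% = missing), the
# shared/exclusive partition across flor samples, and the 70%/80% novelty
# rule over the hit table. Writes results/content/.

suppressMessages(library(florvar))

cov <- read_coverage("results/sim/coverage.tsv")
per_strain <- lapply(split(cov, cov$sample), function(df)
  call_missing(setNames(df$covered_fraction, df$gene_id), threshold = 0.5))
flor <- grep("^flor", names(per_strain), value = TRUE)
res <- shared_missing(per_strain[flor])
message(sprintf("missing in all %d flor samples: %s", length(flor),
                paste(res$shared, collapse = ", ")))
message(sprintf("strain-exclusive losses: %d", sum(lengths(res$exclusive))))

hits <- read_hits("results/sim/hits.tsv")
q <- read.table("results/sim/assembly_genes.tsv", sep = "\t",
                col.names = c("gene_id", "length"))
novel <- novel_genes(hits, setNames(q$length, q$gene_id))
message(sprintf("novel (non-reference) genes: %s", paste(novel, collapse = ", ")))

write_report(list(
  missing_genes = data.frame(sample = rep(names(per_strain), lengths(per_strain)),
                             gene_id = unlist(per_strain, use.names = FALSE)),
  shared_missing = data.frame(gene_id = res$shared),
  novel_genes = data.frame(gene_id = novel)
), "results/content")
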