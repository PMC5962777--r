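# Orchestration: simulate -> filter -> annotate -> stratify -> content ->
# tree as one reproducible run with a manifest and a consolidated summary.

#' Pipeline run configuration
#'
#' Bundles all stage thresholds (validated against their documented ranges)
#' with input/output paths. Either supply the input paths produced by an
#' earlier run / external tools, or set `simulate = TRUE` to generate the
#' synthetic dataset first.
#'
#' @param out_dir Output directory; must differ from the input directory.
#' @param simulate Generate inputs with [generate_dataset()] first?
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param vcf,gff,fasta,groups_file,coverage_file,hits_file,queries_file Input
#'   paths (ignored when `simulate = TRUE`).
#' @param in_clade In-clade group label (default `"flor"`).
#' @param min_depth,min_group_freq,require_biallelic Clade filter thresholds.
#' @param upstream_window,downstream_window Effect windows in bp.
#' @param missing_threshold Breadth threshold for missing genes (strict `<`).
#' @param novelty_identity,novelty_coverage Novelty rule bounds (strict `>`).
#' @param min_missense,min_upstream,min_upstream_strict,min_total Tier
#'   thresholds (defaults 2, 2, 3, 5).
#' @param tree_min_freq,tree_min_depth Tree site-selection bounds.
#' @param seed Seed forwarded to the simulator.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, simulate = FALSE, sim = sim_config(seed = seed),
                       vcf = NULL, gff = NULL, fasta = NULL, groups_file = NULL,
                       coverage_file = NULL, hits_file = NULL, queries_file = NULL,
                       in_clade = "flor",
                       min_depth = 20, min_group_freq = 0.90, require_biallelic = TRUE,
                       upstream_window = 1000, downstream_window = 1000,
                       missing_threshold = 0.5,
                       novelty_identity = 70, novelty_coverage = 0.8,
                       min_missense = 2, min_upstream = 2, min_upstream_strict = 3,
                       min_total = 5,
                       tree_min_freq = 0.9, tree_min_depth = 20,
                       seed = 1) {
  thr <- filter_thresholds(min_depth, min_group_freq, require_biallelic) # validates
  if (missing_threshold <= 0 || missing_threshold > 1) {
    flv_stop("missing_threshold must be in (0, 1]")
  }
  if (novelty_identity < 0 || novelty_identity > 100) flv_stop("novelty_identity must be in [0,100]")
  if (novelty_coverage < 0 || novelty_coverage > 1) flv_stop("novelty_coverage must be in [0,1]")
  if (upstream_window < 0 || downstream_window < 0) flv_stop("windows must be >= 0")
  if (!(tree_min_freq > 0.5 && tree_min_freq <= 1)) flv_stop("tree_min_freq must satisfy 0.5 < f <= 1")
  if (tree_min_depth < 1) flv_stop("tree_min_depth must be >= 1")
  if (any(c(min_missense, min_upstream, min_upstream_strict, min_total) < 0)) {
    flv_stop("tier thresholds must be >= 0")
  }
  if (!simulate) {
    inputs <- c(vcf = vcf, gff = gff, fasta = fasta, groups_file = groups_file)
    if (any(vapply(list(vcf, gff, fasta, groups_file), is.null, logical(1)))) {
      flv_stop("without simulate = TRUE, vcf/gff/fasta/groups_file are required")
    }
    if (normalizePath(out_dir, mustWork = FALSE) %in%
        normalizePath(dirname(unlist(inputs)), mustWork = FALSE)) {
      flv_stop("out_dir must be distinct from the input directories")
    }
  }
  structure(list(out_dir = out_dir, simulate = isTRUE(simulate), sim = sim,
                 vcf = vcf, gff = gff, fasta = fasta, groups_file = groups_file,
                 coverage_file = coverage_file, hits_file = hits_file,
                 queries_file = queries_file, in_clade = in_clade,
                 thresholds = thr,
                 upstream_window = upstream_window, downstream_window = downstream_window,
                 missing_threshold = missing_threshold,
                 novelty_identity = novelty_identity, novelty_coverage = novelty_coverage,
                 min_missense = min_missense, min_upstream = min_upstream,
                 min_upstream_strict = min_upstream_strict, min_total = min_total,
                 tree_min_freq = tree_min_freq, tree_min_depth = tree_min_depth,
                 seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter, annotation, stratification, gene-content and tree stages
#' in order (optionally after simulation), writes all stage outputs plus a
#' `manifest.tsv` (inputs, thresholds, seed, per-file MD5 checksums) and a
#' `summary.tsv` under `config$out_dir`. Identical config and seed yield
#' identical manifest checksums.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with all stage results (`calls`, `effects`,
#'   `category_table`, `dnds`, `loci`, `summaries`, `tiers`, `content`,
#'   `tree`, `summary`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      flv_stop("stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("[%s] done in %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  paths <- if (config$simulate) {
    sim <- stage("simulate", generate_dataset(config$sim, file.path(config$out_dir, "sim")))
    sim$paths
  } else {
    list(vcf = config$vcf, gff = config$gff, genome = config$fasta,
         groups = config$groups_file, coverage = config$coverage_file,
         hits = config$hits_file, queries = config$queries_file)
  }

  groups <- read_groups(paths$groups, in_clade = config$in_clade)
  genome <- read_genome(paths$genome)
  genes <- read_gene_models(paths$gff, config$upstream_window, config$downstream_window)
  vs <- read_variants(paths$vcf, groups)
  say("[inputs] %d sites, %d samples, %d genes", n_sites(vs), length(vs$samples),
      length(genes))

  calls <- stage("filter", call_clade_specific(vs, groups, config$thresholds))
  effects <- stage("annotate", annotate_calls(calls, genes, genome))
  tab <- tabulate_categories(effects)
  ratio <- dn_ds(tab)
  loci <- summarize_loci(calls, genes, genome)
  summaries <- per_gene_summary(effects)
  tiers <- list(
    highly_polymorphic = select_highly_polymorphic(summaries, config$min_missense),
    promoter_mutated = select_promoter_mutated(summaries, config$min_upstream),
    promoter_mutated_strict = select_promoter_mutated(summaries, config$min_upstream_strict),
    extremely_polymorphic = select_extremely_polymorphic(summaries, config$min_total),
    deleterious = select_deleterious(effects)
  )

  content <- NULL
  if (!is.null(paths$coverage)) {
    cov <- read_coverage(paths$coverage)
    per_strain <- lapply(split(cov, cov$sample), function(df) {
      call_missing(stats::setNames(df$covered_fraction, df$gene_id),
                   config$missing_threshold)
    })
    in_strains <- intersect(names(per_strain), in_samples(groups))
    shared <- if (length(in_strains) >= 2) shared_missing(per_strain[in_strains]) else NULL
    novel <- NULL
    if (!is.null(paths$hits) && !is.null(paths$queries)) {
      hits <- read_hits(paths$hits)
      q <- read_tsv_commented(paths$queries, col.names = c("gene_id", "length"),
                              colClasses = c("character", "numeric"))
      novel <- novel_genes(hits, stats::setNames(q$length, q$gene_id),
                           config$novelty_identity, config$novelty_coverage)
    }
    content <- list(per_strain_missing = per_strain, shared = shared, novel = novel)
  }

  tree <- NULL
  snp_mat <- stage("tree", select_tree_sites(vs, config$tree_min_freq, config$tree_min_depth))
  if (nrow(snp_mat$alleles) > 0 && length(vs$samples) >= 3) {
    concatenate_snp_matrix(snp_mat, file.path(config$out_dir, "snp_alignment.fa"))
    tree <- neighbor_joining(p_distance(snp_mat))
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
  }

  # reports
  write_clade_calls(calls, file.path(config$out_dir, "calls.tsv"))
  write_tsv_commented(effects, file.path(config$out_dir, "effects.tsv"))
  write_tsv_commented(data.frame(category = names(unclass(tab)),
                                 count = as.integer(tab), stringsAsFactors = FALSE),
                      file.path(config$out_dir, "category_table.tsv"))
  write_tsv_commented(summaries, file.path(config$out_dir, "gene_summaries.tsv"))
  for (nm in names(tiers)) {
    write_tsv_commented(data.frame(gene_id = tiers[[nm]], stringsAsFactors = FALSE),
                        file.path(config$out_dir, paste0("tier_", nm, ".tsv")))
  }
  if (!is.null(content)) {
    miss_df <- data.frame(
      sample = rep(names(content$per_strain_missing),
                   lengths(content$per_strain_missing)),
      gene_id = unlist(content$per_strain_missing, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv_commented(miss_df, file.path(config$out_dir, "missing_genes.tsv"))
    if (!is.null(content$novel)) {
      write_tsv_commented(data.frame(gene_id = content$novel, stringsAsFactors = FALSE),
                          file.path(config$out_dir, "novel_genes.tsv"))
    }
  }

  summary_df <- data.frame(
    metric = c("n_sites_input", "n_clade_calls", "n_loci", "dnds",
               "n_highly_polymorphic", "n_promoter_mutated",
               "n_promoter_mutated_strict", "n_extremely_polymorphic",
               "n_deleterious_genes", "n_tree_sites"),
    value = c(n_sites(vs), nrow(calls), loci$n_loci, round(ratio, 4),
              length(tiers$highly_polymorphic), length(tiers$promoter_mutated),
              length(tiers$promoter_mutated_strict),
              length(tiers$extremely_polymorphic), length(tiers$deleterious),
              nrow(snp_mat$alleles)),
    stringsAsFactors = FALSE
  )
  write_tsv_commented(summary_df, file.path(config$out_dir, "summary.tsv"))

  outputs <- sort(setdiff(list.files(config$out_dir, recursive = TRUE, full.names = TRUE),
                          file.path(config$out_dir, "manifest.tsv")))
  manifest <- data.frame(
    file = sub(paste0("^", config$out_dir, "/?"), "", outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  manifest <- rbind(manifest,
                    data.frame(file = "config:seed", md5 = as.character(config$seed),
                               stringsAsFactors = FALSE))
  write_tsv_commented(manifest, file.path(config$out_dir, "manifest.tsv"))
  say("[summary] %d clade calls in %d loci; dN/dS = %.3f; %d tree sites",
      nrow(calls), loci$n_loci, ratio, nrow(snp_mat$alleles))

  invisible(list(calls = calls, effects = effects, category_table = tab,
                 dnds = ratio, loci = loci, summaries = summaries, tiers = tiers,
                 content = content, snp_matrix = snp_mat, tree = tree,
                 summary = summary_df, manifest = manifest))
}
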