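# Truth-annotated synthetic dataset generator.
#
# Emulates the statistical structure the downstream analysis assumes: a small
# single-chromosome genome with annotated (optionally intron-containing) genes
# on both strands, an in-clade ("flor") and an out-clade ("wine") of samples,
# planted clade-fixed biallelic variants spanning every effect category,
# shared-polymorphism decoys, heterozygous-like (~0.5 frequency) decoys,
# low-depth decoys, planted gene deletions in the in-clade, and novel-gene hit
# tables — all accompanied by machine-readable truth files.

#' Configuration for the synthetic dataset generator
#'
#' All randomness flows from the single `seed`, so identical configurations
#' produce byte-identical output files.
#'
#' Default sizes mirror the study conditions the generator emulates at desk
#' scale: an in-clade of 3 deeply sequenced flor-analog samples against a
#' larger wine-analog out-clade, overdispersed short-read depth well above the
#' 20x filter bound, near-fixed clade alleles (small per-site read-frequency
#' jitter), and decoy classes exercising every rejection clause of the
#' discrimination filter.
#'
#' @param genome_length Genome size in bp (single chromosome `chr1`).
#' @param n_genes Number of non-overlapping genes to place.
#' @param intron_prob Probability that a gene carries one intron.
#' @param n_clade_a_samples,n_clade_b_samples Samples in the in-clade
#'   (`flor`) and out-clade (`wine`).
#' @param n_planted_clade_variants Clade-fixed biallelic truth sites.
#' @param n_shared_variants Shared-polymorphism decoy sites (high-frequency in
#'   a sample subset straddling, or properly inside, one clade).
#' @param n_het_like_sites Decoy sites with per-sample major-allele frequency
#'   drawn in \[0.4, 0.6\] for a sample subset.
#' @param n_low_depth_sites Decoy sites with a perfect clade pattern but at
#'   least one sample forced below 20x depth.
#' @param mean_depth Mean per-sample depth (reads; must exceed 20).
#' @param depth_dispersion Negative-binomial size parameter of the depth law.
#' @param support_noise Per-site read-frequency jitter: fixed alleles are
#'   drawn in `[1 - support_noise, 1]`.
#' @param n_deleted_genes_clade_a Genes deleted (coverage < 0.5) in every
#'   in-clade sample.
#' @param n_novel_genes Non-reference gene candidates whose hit-table rows
#'   fall below the 70%/80% novelty rule.
#' @param upstream_window,downstream_window Window sizes (bp) used when
#'   placing upstream/downstream/intergenic truth variants.
#' @param seed Integer seed governing all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000, n_genes = 30, intron_prob = 0.15,
                       n_clade_a_samples = 3, n_clade_b_samples = 5,
                       n_planted_clade_variants = 50, n_shared_variants = 200,
                       n_het_like_sites = 50, n_low_depth_sites = 30,
                       mean_depth = 60, depth_dispersion = 8,
                       support_noise = 0.02, n_deleted_genes_clade_a = 3,
                       n_novel_genes = 2, upstream_window = 1000,
                       downstream_window = 1000, seed = 1) {
  cfg <- list(genome_length = genome_length, n_genes = n_genes,
              intron_prob = intron_prob,
              n_clade_a_samples = n_clade_a_samples,
              n_clade_b_samples = n_clade_b_samples,
              n_planted_clade_variants = n_planted_clade_variants,
              n_shared_variants = n_shared_variants,
              n_het_like_sites = n_het_like_sites,
              n_low_depth_sites = n_low_depth_sites,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              support_noise = support_noise,
              n_deleted_genes_clade_a = n_deleted_genes_clade_a,
              n_novel_genes = n_novel_genes,
              upstream_window = upstream_window,
              downstream_window = downstream_window, seed = seed)
  counts <- c("n_genes", "n_clade_a_samples", "n_clade_b_samples",
              "n_planted_clade_variants", "n_shared_variants",
              "n_het_like_sites", "n_low_depth_sites",
              "n_deleted_genes_clade_a", "n_novel_genes")
  for (nm in counts) if (cfg[[nm]] < 0) flv_stop("%s must be >= 0", nm)
  if (cfg$n_clade_a_samples < 1 || cfg$n_clade_b_samples < 1) {
    flv_stop("each clade needs >= 1 sample")
  }
  if (cfg$genome_length < 50 * cfg$n_genes) {
    flv_stop("genome_length must be >= 50 x n_genes")
  }
  if (!(cfg$intron_prob >= 0 && cfg$intron_prob <= 1)) flv_stop("intron_prob must be in [0,1]")
  if (!(cfg$support_noise >= 0 && cfg$support_noise <= 1)) flv_stop("support_noise must be in [0,1]")
  if (cfg$mean_depth <= 20) flv_stop("mean_depth must exceed the 20x depth floor")
  if (cfg$depth_dispersion <= 0) flv_stop("depth_dispersion must be > 0")
  if (cfg$n_deleted_genes_clade_a > cfg$n_genes) flv_stop("more deleted genes than genes")
  structure(cfg, class = "sim_config")
}

DEPTH_FLOOR <- 20L

sim_sample_names <- function(config) {
  list(a = sprintf("flor_%02d", seq_len(config$n_clade_a_samples)),
       b = sprintf("wine_%02d", seq_len(config$n_clade_b_samples)))
}

# Lay out n_genes non-overlapping genes in equal genome blocks.
sim_gene_layout <- function(config) {
  L <- config$genome_length %/% max(config$n_genes, 1L)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    n_codons <- sample(60:220, 1)
    cds_len <- 3L * n_codons
    has_intron <- stats::runif(1) < config$intron_prob
    intron_len <- if (has_intron) sample(40:80, 1) else 0L
    glen <- cds_len + intron_len
    block_start <- (i - 1L) * L + 1L
    max_off <- L - glen - 100L
    if (max_off < 100L) {
      flv_stop("genome_length too small to place %d genes of up to %d bp", config$n_genes, glen)
    }
    gstart <- block_start + sample(100:max_off, 1)
    cds <- if (has_intron) {
      split_at <- 3L * sample(20:(n_codons - 20), 1)  # intron between codons
      rbind(c(gstart, gstart + split_at - 1L),
            c(gstart + split_at + intron_len, gstart + glen - 1L))
    } else {
      rbind(c(gstart, gstart + glen - 1L))
    }
    colnames(cds) <- c("start", "end")
    genes[[i]] <- gene_model(sprintf("gene%03d", i), "chr1",
                             sample(c("+", "-"), 1), cds,
                             config$upstream_window, config$downstream_window)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "gene_models")
}

# How many of the planted positions a feature geometry check claims for each
# requested effect category. Proportions loosely follow the category spectrum
# observed for clade-specific yeast variants (missense-heavy, then upstream
# and synonymous, few deleterious).
spectrum_allocation <- function(n) {
  cats <- c(missense = 0.42, synonymous = 0.25, upstream = 0.20,
            downstream = 0.05, frameshift = 0.02, intron = 0.02,
            intergenic = 0.02, stop_splice = 0.02)
  if (n < length(cats)) {
    return(stats::setNames(c(rep(1L, n), rep(0L, length(cats) - n)), names(cats)))
  }
  base <- rep(1L, length(cats))
  extra <- n - length(cats)
  add <- floor(extra * cats / sum(cats))
  alloc <- base + add
  short <- n - sum(alloc)
  k <- 1L
  while (short > 0) { alloc[k] <- alloc[k] + 1L; short <- short - 1L; k <- k %% length(cats) + 1L }
  stats::setNames(as.integer(alloc), names(cats))
}

# Is pos inside any already-claimed span (with a small guard band)?
pos_free <- function(pos, used, pad = 2L) {
  all(abs(used - pos) > pad)
}

#' Plan clade-specific variant placements covering an effect spectrum
#'
#' Chooses genomic positions and ref/alt alleles so that each requested effect
#' category has at least one planted instance. Placement geometry is computed
#' directly from gene coordinates and local codon arithmetic; the downstream
#' classifier is not consulted, so truth labels stay independent.
#'
#' @param config A [sim_config()].
#' @param genes Gene models (as from [sim_gene_layout()]).
#' @param genome Genome list.
#' @param requests Named integer vector category -> count; default allocates
#'   `n_planted_clade_variants` across all eight categories.
#' @return Data frame `pos`, `ref`, `alt`, `category`, `gene_id`.
#' @export
plant_effect_spectrum <- function(config, genes, genome,
                                  requests = spectrum_allocation(config$n_planted_clade_variants)) {
  requests <- requests[requests > 0]
  bad <- setdiff(names(requests), CATEGORY_LEVELS)
  if (length(bad) > 0) flv_stop("unknown effect category requested: %s", bad[1])
  used <- numeric(0)
  out <- list()
  glen <- config$genome_length

  with_introns <- Filter(function(g) nrow(g$introns) > 0, genes)
  # feature membership helpers over the whole gene set
  in_any_gene <- function(p) any(vapply(genes, function(g) p >= g$start && p <= g$end, logical(1)))
  window_hits <- function(p) {
    sum(vapply(genes, function(g) {
      up <- gene_upstream_interval(g); dn <- gene_downstream_interval(g)
      (!anyNA(up) && p >= up[1] && p <= up[2]) || (!anyNA(dn) && p >= dn[1] && p <= dn[2])
    }, logical(1)))
  }
  upstream_of_one <- function(p) {
    hits <- vapply(genes, function(g) {
      up <- gene_upstream_interval(g)
      !anyNA(up) && p >= up[1] && p <= up[2]
    }, logical(1))
    dnhits <- vapply(genes, function(g) {
      dn <- gene_downstream_interval(g)
      !anyNA(dn) && p >= dn[1] && p <= dn[2]
    }, logical(1))
    if (sum(hits) == 1 && sum(dnhits) == 0) names(genes)[hits] else NULL
  }
  downstream_of_one <- function(p) {
    dnhits <- vapply(genes, function(g) {
      dn <- gene_downstream_interval(g)
      !anyNA(dn) && p >= dn[1] && p <= dn[2]
    }, logical(1))
    uphits <- vapply(genes, function(g) {
      up <- gene_upstream_interval(g)
      !anyNA(up) && p >= up[1] && p <= up[2]
    }, logical(1))
    if (sum(dnhits) == 1 && sum(uphits) == 0) names(genes)[dnhits] else NULL
  }

  place_coding <- function(category) {
    # try random genes/codons until the requested codon-level effect is found
    for (try in 1:4000) {
      g <- genes[[sample(length(genes), 1)]]
      map <- cds_map(g, genome)
      nc <- length(map$bases) %/% 3L
      ci <- sample(nc, 1) - 1L
      span <- (ci * 3L + 1L):(ci * 3L + 3L)
      oc <- paste(map$bases[span], collapse = "")
      old <- codon_aa(oc)
      if (old == "*") next
      within <- sample(3L, 1)
      j <- span[within]
      gp <- map$gpos[j]
      if (!pos_free(gp, used)) next
      for (b in sample(DNA_BASES)) {
        tb <- if (g$strand == "-") dna_complement(b) else b
        if (tb == map$bases[j]) next
        ncod <- oc
        substr(ncod, within, within) <- tb
        new <- codon_aa(ncod)
        hit <- switch(category,
          synonymous = new == old,
          missense = new != old && new != "*",
          stop_splice = new == "*",
          FALSE)
        if (hit) {
          return(data.frame(pos = gp, ref = genome_bases(genome, "chr1", gp),
                            alt = b, category = category, gene_id = g$gene_id,
                            stringsAsFactors = FALSE))
        }
      }
    }
    flv_stop("could not place a '%s' variant on the synthetic genes", category)
  }

  place_one <- function(category) {
    if (category %in% c("missense", "synonymous", "stop_splice")) {
      return(place_coding(category))
    }
    if (category == "frameshift") {
      for (try in 1:2000) {
        g <- genes[[sample(length(genes), 1)]]
        k <- sample(nrow(g$cds), 1)
        if (g$cds[k, 2] - g$cds[k, 1] < 10) next
        p <- sample(seq(g$cds[k, 1] + 1, g$cds[k, 2] - 2), 1)
        if (!pos_free(p, used) || !pos_free(p + 1, used)) next
        return(data.frame(pos = p, ref = genome_substr(genome, "chr1", p, p + 1),
                          alt = genome_bases(genome, "chr1", p),
                          category = "frameshift", gene_id = g$gene_id,
                          stringsAsFactors = FALSE))
      }
      flv_stop("could not place a 'frameshift' variant")
    }
    if (category == "intron") {
      if (length(with_introns) == 0) {
        flv_stop("category 'intron' unplaceable: no gene carries an intron (intron_prob too low)")
      }
      for (try in 1:2000) {
        g <- with_introns[[sample(length(with_introns), 1)]]
        iv <- g$introns[sample(nrow(g$introns), 1), ]
        if (iv[2] - iv[1] < 8) next
        p <- sample(seq(iv[1] + 3, iv[2] - 3), 1)   # clear of the 2 nt splice region
        if (!pos_free(p, used)) next
        ref <- genome_bases(genome, "chr1", p)
        return(data.frame(pos = p, ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1),
                          category = "intron", gene_id = g$gene_id,
                          stringsAsFactors = FALSE))
      }
      flv_stop("could not place an 'intron' variant")
    }
    if (category %in% c("upstream", "downstream")) {
      for (try in 1:5000) {
        p <- sample(glen, 1)
        if (in_any_gene(p) || !pos_free(p, used)) next
        gid <- if (category == "upstream") upstream_of_one(p) else downstream_of_one(p)
        if (is.null(gid)) next
        ref <- genome_bases(genome, "chr1", p)
        return(data.frame(pos = p, ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1),
                          category = category, gene_id = gid, stringsAsFactors = FALSE))
      }
      flv_stop("could not place an '%s' variant (windows may tile the genome)", category)
    }
    if (category == "intergenic") {
      for (try in 1:5000) {
        p <- sample(glen, 1)
        if (in_any_gene(p) || window_hits(p) > 0 || !pos_free(p, used)) next
        ref <- genome_bases(genome, "chr1", p)
        return(data.frame(pos = p, ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1),
                          category = "intergenic", gene_id = NA_character_,
                          stringsAsFactors = FALSE))
      }
      flv_stop("category 'intergenic' unplaceable: no position escapes all genes and windows")
    }
    flv_stop("unhandled category '%s'", category)
  }

  for (category in names(requests)) {
    for (r in seq_len(requests[[category]])) {
      row <- place_one(category)
      used <- c(used, seq(row$pos, row$pos + nchar(row$ref) - 1L))
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      category = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Depth draw: floored negative binomial (overdispersed short-read coverage,
# never below the filter's 20x bound except at planted low-depth sites).
draw_depths <- function(n, config) {
  DEPTH_FLOOR + stats::rnbinom(n, size = config$depth_dispersion,
                               mu = config$mean_depth - DEPTH_FLOOR)
}

# Allele read counts from a target alt frequency: AO = round(f * DP),
# RO = DP - AO, so RO + AO == DP exactly.
split_reads <- function(depth, alt_freq) {
  ao <- round(alt_freq * depth)
  c(ref = depth - ao, alt = ao)
}

jitter_high <- function(n, noise) 1 - stats::runif(n, 0, noise)
jitter_low <- function(n, noise) stats::runif(n, 0, noise)

#' Generate the complete synthetic dataset
#'
#' Writes, under `dir`: `genome.fa`, `genes.gff3`, `calls.vcf` (freebayes
#' dialect, FORMAT `GT:DP:RO:AO`), `coverage.tsv`, `hits.tsv`,
#' `assembly_genes.tsv` (candidate gene lengths for novelty detection),
#' `groups.tsv`, and the truth tables `truth_sites.tsv`,
#' `truth_deleted_genes.tsv`, `truth_novel_genes.tsv`. Identical configs
#' (including seed) produce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created; must be writable).
#' @return Invisibly, a list with `truth` (the truth tables as data frames),
#'   `paths` (named file paths), `genes`, `genome`, and `groups`.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) flv_stop("cannot create output directory %s", dir)
  set.seed(config$seed)

  genome <- list(chr1 = paste(sample(DNA_BASES, config$genome_length, replace = TRUE),
                              collapse = ""))
  genes <- sim_gene_layout(config)
  sn <- sim_sample_names(config)
  samples <- c(sn$a, sn$b)
  groups <- group_config(stats::setNames(rep(c("flor", "wine"), c(length(sn$a), length(sn$b))),
                                         samples), in_clade = "flor")

  plan <- plant_effect_spectrum(config, genes, genome)
  used <- if (nrow(plan) > 0) {
    unlist(mapply(function(p, r) seq(p, p + nchar(r) - 1L), plan$pos, plan$ref,
                  SIMPLIFY = FALSE))
  } else numeric(0)

  draw_decoy_positions <- function(n) {
    pos <- integer(0)
    while (length(pos) < n) {
      p <- sample(config$genome_length, 1)
      if (pos_free(p, c(used, pos))) pos <- c(pos, p)
    }
    pos
  }
  shared_pos <- draw_decoy_positions(config$n_shared_variants)
  used <- c(used, shared_pos)
  het_pos <- draw_decoy_positions(config$n_het_like_sites)
  used <- c(used, het_pos)
  low_pos <- draw_decoy_positions(config$n_low_depth_sites)

  rand_alt <- function(p) {
    ref <- genome_bases(genome, "chr1", p)
    vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1),
           USE.NAMES = FALSE)
  }

  rows <- list()
  add_site <- function(pos, ref, alt, type, clade_allele, category,
                       alt_freqs, depths) {
    rows[[length(rows) + 1L]] <<- list(pos = pos, ref = ref, alt = alt,
                                       type = type, clade_allele = clade_allele,
                                       category = category,
                                       alt_freqs = alt_freqs, depths = depths)
  }

  ns <- length(samples)
  na <- length(sn$a)
  noise <- config$support_noise

  # clade-specific truth sites: alt fixed in clade A, ref fixed in clade B
  for (i in seq_len(nrow(plan))) {
    af <- c(jitter_high(na, noise), jitter_low(ns - na, noise))
    add_site(plan$pos[i], plan$ref[i], plan$alt[i], "clade_specific",
             plan$alt[i], plan$category[i], af, draw_depths(ns, config))
  }
  # shared polymorphisms: fixed alt in a subset that is neither clade exactly
  for (p in shared_pos) {
    repeat {
      carriers <- which(stats::runif(ns) < stats::runif(1, 0.2, 0.8))
      if (length(carriers) == 0) next
      if (identical(sort(carriers), seq_len(na))) next          # exactly clade A
      if (identical(sort(carriers), seq(na + 1L, ns))) next     # exactly clade B
      break
    }
    af <- jitter_low(ns, noise)
    af[carriers] <- jitter_high(length(carriers), noise)
    add_site(p, genome_bases(genome, "chr1", p), rand_alt(p), "shared",
             NA_character_, NA_character_, af, draw_depths(ns, config))
  }
  # het-like sites: a non-empty subset sits at ~0.5 frequency
  for (p in het_pos) {
    carriers <- sample(ns, sample(ns, 1))
    af <- jitter_low(ns, noise)
    af[carriers] <- stats::runif(length(carriers), 0.4, 0.6)
    add_site(p, genome_bases(genome, "chr1", p), rand_alt(p), "het_like",
             NA_character_, NA_character_, af, draw_depths(ns, config))
  }
  # low-depth sites: perfect clade pattern, but >= 1 sample under 20x
  for (p in low_pos) {
    af <- c(jitter_high(na, noise), jitter_low(ns - na, noise))
    d <- draw_depths(ns, config)
    k <- sample(ns, sample(2, 1))
    d[k] <- sample(5:19, length(k), replace = TRUE)
    add_site(p, genome_bases(genome, "chr1", p), rand_alt(p), "low_depth",
             NA_character_, NA_character_, af, d)
  }

  # assemble the variant_set in genomic order
  ord <- order(vapply(rows, `[[`, numeric(1), "pos"))
  rows <- rows[ord]
  sites <- data.frame(
    chrom = rep("chr1", length(rows)),
    pos = vapply(rows, `[[`, numeric(1), "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alts = vapply(rows, `[[`, "", "alt"),
    stringsAsFactors = FALSE
  )
  dp <- do.call(rbind, lapply(rows, `[[`, "depths"))
  if (length(rows) == 0) dp <- matrix(numeric(0), 0, ns)
  ar <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    counts <- vapply(seq_len(ns), function(s) split_reads(r$depths[s], r$alt_freqs[s]),
                     numeric(2))
    m <- matrix(counts, nrow = 2)
    rownames(m) <- c(r$ref, r$alt)
    colnames(m) <- samples
    m
  })
  vs <- variant_set(sites, samples, dp, ar)

  # gene deletions in every clade-A sample
  deleted <- if (config$n_deleted_genes_clade_a > 0) {
    sort(sample(names(genes), config$n_deleted_genes_clade_a))
  } else character(0)
  cov <- expand.grid(gene_id = names(genes), sample = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cov <- cov[order(cov$gene_id, cov$sample), ]
  is_del <- cov$gene_id %in% deleted & cov$sample %in% sn$a
  cov$covered_fraction <- round(ifelse(is_del, stats::runif(nrow(cov), 0.05, 0.45),
                                       stats::runif(nrow(cov), 0.90, 1.00)), 4)

  # hit table + candidate gene lengths for novelty detection
  ref_genes <- names(genes)
  novel_ids <- if (config$n_novel_genes > 0) {
    sprintf("novel%03d", seq_len(config$n_novel_genes))
  } else character(0)
  qlen <- c(vapply(genes, function(g) g$end - g$start + 1, numeric(1)),
            stats::setNames(sample(300:1500, length(novel_ids), replace = TRUE), novel_ids))
  hit_rows <- list()
  for (q in ref_genes) {
    al <- round(qlen[[q]] * stats::runif(1, 0.9, 1.0))
    pid <- round(stats::runif(1, 92, 100), 2)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = q, subject_id = paste0("S288C_", q), percent_identity = pid,
      alignment_length = al, mismatches = round(al * (100 - pid) / 100),
      gap_opens = 0, q_start = 1, q_end = al, s_start = 1, s_end = al,
      evalue = 1e-50, bit_score = round(al * 1.8), stringsAsFactors = FALSE)
  }
  for (q in novel_ids) {
    if (stats::runif(1) < 0.5) next  # some novels have no hit at all
    al <- round(qlen[[q]] * stats::runif(1, 0.2, 0.75))
    pid <- round(stats::runif(1, 40, 65), 2)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = q, subject_id = "S288C_misc", percent_identity = pid,
      alignment_length = al, mismatches = round(al * (100 - pid) / 100),
      gap_opens = 1, q_start = 1, q_end = al, s_start = 1, s_end = al,
      evalue = 1e-3, bit_score = round(al * 0.9), stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else
    data.frame(query_id = character(0), subject_id = character(0),
               percent_identity = numeric(0), alignment_length = numeric(0),
               mismatches = numeric(0), gap_opens = numeric(0),
               q_start = numeric(0), q_end = numeric(0), s_start = numeric(0),
               s_end = numeric(0), evalue = numeric(0), bit_score = numeric(0))

  # truth tables
  truth_sites <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alts,
    type = vapply(rows, `[[`, "", "type"),
    clade_allele = vapply(rows, `[[`, "", "clade_allele"),
    category = vapply(rows, `[[`, "", "category"),
    stringsAsFactors = FALSE
  )
  truth_deleted <- expand.grid(sample = sn$a, gene_id = deleted,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth_deleted <- truth_deleted[order(truth_deleted$sample, truth_deleted$gene_id), ,
                                 drop = FALSE]
  truth_novel <- data.frame(gene_id = novel_ids, stringsAsFactors = FALSE)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "calls.vcf"),
    coverage = file.path(dir, "coverage.tsv"),
    hits = file.path(dir, "hits.tsv"),
    queries = file.path(dir, "assembly_genes.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_deleted = file.path(dir, "truth_deleted_genes.tsv"),
    truth_novel = file.path(dir, "truth_novel_genes.tsv")
  )
  write_genome(genome, paths$genome)
  write_gene_models(genes, paths$gff)
  write_variants(vs, paths$vcf)
  write_tsv_commented(cov, paths$coverage)
  write_tsv_commented(hits, paths$hits)
  write_tsv_commented(data.frame(gene_id = names(qlen), length = unname(qlen),
                                 stringsAsFactors = FALSE), paths$queries)
  write_groups(groups, paths$groups)
  write_tsv_commented(truth_sites, paths$truth_sites)
  write_tsv_commented(truth_deleted, paths$truth_deleted)
  write_tsv_commented(truth_novel, paths$truth_novel)

  invisible(list(
    truth = list(sites = truth_sites, deleted_genes = truth_deleted,
                 novel_genes = truth_novel),
    paths = paths, genes = genes, genome = genome, groups = groups,
    variant_set = vs, coverage = cov, hits = hits,
    query_lengths = stats::setNames(unname(qlen), names(qlen))
  ))
}
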