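# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately take the dumbest correct route (scalar loops, full
# sequence rebuilds, per-base bitmaps) so they share no code path with the
# implementations they check.

## ---- fixtures ----------------------------------------------------------

# A gene model without going through GFF3 (internal constructor).
make_gene <- function(gene_id = "geneA", chrom = "chr1", strand = "+",
                      cds = rbind(c(101, 400)), up = 1000, dn = 1000) {
  colnames(cds) <- c("start", "end")
  florvar:::gene_model(gene_id, chrom, strand, cds, up, dn)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A random gene embedded in its own little chromosome; returns list(gene, genome).
random_gene_fixture <- function(strand = sample(c("+", "-"), 1),
                                n_codons = sample(40:120, 1),
                                with_intron = sample(c(TRUE, FALSE), 1)) {
  intron_len <- if (with_intron) sample(30:60, 1) else 0L
  cds_len <- 3L * n_codons
  gstart <- 101L
  cds <- if (with_intron) {
    cut <- 3L * sample(10:(n_codons - 10), 1)
    rbind(c(gstart, gstart + cut - 1L),
          c(gstart + cut + intron_len, gstart + cds_len + intron_len - 1L))
  } else {
    rbind(c(gstart, gstart + cds_len - 1L))
  }
  glen <- 200L + cds_len + intron_len
  genome <- list(chr1 = random_dna(glen))
  list(gene = make_gene("geneA", strand = strand, cds = cds, up = 50, dn = 50),
       genome = genome)
}

# A one-site variant set from per-sample (depth, named allele counts).
make_site_vs <- function(ref, alts, dp, counts, chrom = "chr1", pos = 100L) {
  samples <- names(dp)
  alleles <- c(ref, alts)
  m <- matrix(NA_real_, length(alleles), length(samples),
              dimnames = list(alleles, samples))
  for (s in samples) m[, s] <- counts[[s]]
  variant_set(
    data.frame(chrom = chrom, pos = pos, ref = ref,
               alts = paste(alts, collapse = ","), stringsAsFactors = FALSE),
    samples,
    matrix(dp, 1, dimnames = list(NULL, samples)),
    list(m)
  )
}

# A generator configuration with nothing planted.
empty_cfg <- function(seed = 7) {
  sim_config(n_planted_clade_variants = 0, n_shared_variants = 0,
             n_het_like_sites = 0, n_low_depth_sites = 0,
             n_deleted_genes_clade_a = 0, n_novel_genes = 0, seed = seed)
}

two_clade_groups <- function(n_in = 3, n_out = 2) {
  s <- c(sprintf("flor_%02d", seq_len(n_in)), sprintf("wine_%02d", seq_len(n_out)))
  group_config(setNames(rep(c("flor", "wine"), c(n_in, n_out)), s), "flor")
}

## ---- clade filter oracle ----------------------------------------------

# Scalar re-evaluation of the four filter clauses, enumerating every allele
# as the candidate clade allele.
oracle_clade_site <- function(ar, dp, ins, outs, min_depth = 20,
                              min_freq = 0.9, biallelic = TRUE) {
  for (s in c(ins, outs)) {
    if (is.na(dp[s]) || dp[s] < min_depth) return(list(pass = FALSE))
  }
  freq <- function(allele, s) {
    if (dp[s] <= 0) return(NA_real_)
    ar[allele, s] / dp[s]
  }
  alleles <- rownames(ar)
  if (biallelic) {
    attained <- character(0)
    for (a in alleles) {
      for (s in c(ins, outs)) {
        if (!is.na(freq(a, s)) && freq(a, s) >= min_freq) {
          attained <- union(attained, a)
        }
      }
    }
    if (length(attained) != 2) return(list(pass = FALSE))
  }
  for (a in alleles) {
    ok_in <- TRUE
    for (s in ins) if (is.na(freq(a, s)) || freq(a, s) < min_freq) ok_in <- FALSE
    if (!ok_in) next
    ok_out <- TRUE
    for (s in outs) {
      found <- FALSE
      for (b in setdiff(alleles, a)) {
        if (!is.na(freq(b, s)) && freq(b, s) >= min_freq) found <- TRUE
      }
      if (!found) ok_out <- FALSE
    }
    if (ok_out) return(list(pass = TRUE, allele = a))
  }
  list(pass = FALSE)
}

# Random multi-allelic site for oracle-equivalence sweeps. Mixes clade-like,
# near-miss and chaotic read patterns so both branches get exercised.
random_site <- function(samples, n_in) {
  n <- length(samples)
  n_alleles <- sample(2:4, 1)
  alleles <- sample(c("A", "C", "G", "T", "AT", "TAC"), n_alleles)
  dp <- sample(c(10:40, 60), n, replace = TRUE)
  if (runif(1) < 0.05) dp[sample(n, 1)] <- NA
  m <- matrix(0, n_alleles, n, dimnames = list(alleles, samples))
  style <- runif(1)
  if (style < 0.2) dp <- sample(15:60, n, replace = TRUE)  # clade-like cases
  for (s in seq_len(n)) {
    if (is.na(dp[s])) { m[, s] <- NA; next }
    if (style < 0.2) {
      # clade-patterned: in-clade near-fixed on allele 1, out-clade on allele
      # 2; depth/frequency jitter still rejects a share of these
      top <- if (s <= n_in) 1L else 2L
      f <- runif(1, 0.88, 1)
      m[top, s] <- round(f * dp[s])
      m[if (top == 1L) 2L else 1L, s] <- dp[s] - m[top, s]
    } else if (style < 0.5) {
      # near-fixed on a random allele per sample
      top <- sample(n_alleles, 1)
      f <- runif(1, 0.85, 1)
      m[top, s] <- round(f * dp[s])
      rest <- dp[s] - m[top, s]
      others <- setdiff(seq_len(n_alleles), top)
      m[others[1], s] <- rest
    } else {
      pr <- as.vector(stats::rmultinom(1, dp[s], runif(n_alleles)))
      m[, s] <- pr
    }
  }
  list(ar = m, dp = setNames(dp, samples), ref = alleles[1],
       alts = alleles[-1])
}

## ---- effect oracle (full-CDS rebuild + Biostrings translation) ---------

oracle_classify_substitution <- function(gene, genome, pos, ref, alt) {
  chrom <- genome[[gene$chrom]]
  stopifnot(substr(chrom, pos, pos + nchar(ref) - 1) == ref)
  mutant <- chrom
  substr(mutant, pos, pos + nchar(alt) - 1) <- alt
  cds_seq <- function(src) {
    parts <- apply(gene$cds, 1, function(iv) substr(src, iv[1], iv[2]))
    s <- paste(parts, collapse = "")
    if (gene$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  tr <- function(s) {
    n <- (nchar(s) %/% 3) * 3
    # literal codon table: the gene models carry no initiator-codon semantics
    as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                       if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  aa_old <- strsplit(tr(cds_seq(chrom)), "")[[1]]
  aa_new <- strsplit(tr(cds_seq(mutant)), "")[[1]]
  if (identical(aa_old, aa_new)) return("synonymous")
  if (any(aa_new == "*" & aa_old != "*")) return("stop_splice")
  if (any(aa_old == "*" & aa_new != "*")) return("stop_splice")
  "missense"
}

## ---- coverage bitmap oracle --------------------------------------------

oracle_coverage_fraction <- function(intervals, gene) {
  bitmap <- rep(FALSE, gene$end - gene$start + 1)
  for (k in seq_len(nrow(intervals))) {
    idx <- seq(intervals$start[k], intervals$end[k]) - gene$start + 1
    bitmap[idx] <- TRUE
  }
  mean(bitmap)
}

## ---- additive trees ------------------------------------------------------

# Random unrooted binary tree and its (exactly additive) leaf distances.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
}
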