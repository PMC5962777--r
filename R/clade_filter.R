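# The two-clade discrimination filter: the core computation of the pipeline.
#
# A site is clade-specific when, at >= min_depth reads in every sample, one
# allele reaches >= min_group_freq read frequency in every in-clade sample
# while every out-clade sample supports some *different* allele at the same
# frequency bound (out-clade samples need not agree with each other).

#' Filter thresholds for the clade discrimination filter
#'
#' Defaults follow the read-frequency filter used for flor-vs-wine variant
#' discrimination: minimum 20x depth at the variant position in every sample
#' and 90% read-frequency support, with the biallelic restriction on.
#'
#' @param min_depth Minimum per-sample read depth (inclusive; default 20).
#' @param min_group_freq Minimum per-sample read frequency of the supporting
#'   allele (inclusive; default 0.90; must satisfy 0.5 < f <= 1 so the
#'   supporting allele is unique within a sample).
#' @param require_biallelic If `TRUE` (default), require that exactly two
#'   distinct alleles reach the frequency bound across all samples.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_depth = 20, min_group_freq = 0.90,
                              require_biallelic = TRUE) {
  if (min_depth < 1) flv_stop("min_depth must be >= 1")
  if (!(min_group_freq > 0.5 && min_group_freq <= 1)) {
    flv_stop("min_group_freq must satisfy 0.5 < f <= 1 (got %g)", min_group_freq)
  }
  structure(list(min_depth = min_depth, min_group_freq = min_group_freq,
                 require_biallelic = isTRUE(require_biallelic)),
            class = "filter_thresholds")
}

#' Read frequency of one allele in one sample
#'
#' @param allele_reads Named numeric vector of per-allele read counts.
#' @param depth Total read depth (must be > 0).
#' @param allele Allele string; an allele absent from `allele_reads` has
#'   frequency 0.
#' @return `allele_reads[allele] / depth`.
#' @export
sample_allele_freq <- function(allele_reads, depth, allele) {
  if (is.na(depth) || depth <= 0) {
    flv_stop("allele frequency undefined at depth %s", as.character(depth))
  }
  r <- allele_reads[allele]
  if (is.na(r)) r <- 0
  unname(r / depth)
}

#' Call clade-specific variants
#'
#' Applies the four-clause discrimination predicate to every site of a
#' multi-sample variant set: (i) every sample in both clades has depth >=
#' `min_depth` and carries data; (ii) one allele reaches >= `min_group_freq`
#' in every in-clade sample; (iii) every out-clade sample has some allele
#' different from it at >= `min_group_freq` (allowed to differ between
#' out-clade samples); (iv) if `require_biallelic`, exactly two distinct
#' alleles reach the bound across all samples.
#'
#' @param vs A [variant_set()].
#' @param groups A [group_config()]; both clades must be non-empty and all
#'   grouped samples present in `vs`.
#' @param thresholds A [filter_thresholds()].
#' @return Object of class `clade_calls`: a data frame in genomic order with
#'   columns `chrom`, `pos`, `ref`, `alts`, `clade_allele`, `out_alleles`
#'   (comma-joined), and an attribute `per_sample_freq` (calls x samples
#'   matrix of the clade allele's read frequency).
#' @export
call_clade_specific <- function(vs, groups, thresholds = filter_thresholds()) {
  stopifnot(inherits(vs, "variant_set"), inherits(groups, "group_config"))
  ins <- in_samples(groups)
  outs <- out_samples(groups)
  if (length(ins) < 1 || length(outs) < 1) flv_stop("both clades must contain >= 1 sample")
  missing <- setdiff(c(ins, outs), vs$samples)
  if (length(missing) > 0) {
    flv_stop("grouped samples absent from variant set: %s", paste(missing, collapse = ", "))
  }
  t <- thresholds
  keep <- logical(n_sites(vs))
  clade_allele <- character(n_sites(vs))
  out_alleles <- character(n_sites(vs))
  freq_rows <- list()
  used <- c(ins, outs)
  for (i in seq_len(n_sites(vs))) {
    dp <- vs$dp[i, used]
    if (anyNA(dp) || any(dp < t$min_depth)) next
    m <- vs$ar[[i]][, used, drop = FALSE]
    fr <- sweep(m, 2, dp, "/")
    passing <- fr >= t$min_group_freq           # alleles x samples
    # clause (ii): allele fixed across the in-clade
    a_ok <- which(rowSums(passing[, ins, drop = FALSE]) == length(ins))
    if (length(a_ok) == 0) next
    a <- rownames(m)[a_ok[1]]                   # unique since min_group_freq > 0.5
    # clause (iii): every out-clade sample supports some allele != a
    other <- passing[rownames(m) != a, outs, drop = FALSE]
    if (!all(colSums(other) >= 1)) next
    # clause (iv): biallelic across all samples
    if (t$require_biallelic) {
      attained <- rownames(m)[rowSums(passing) > 0]
      if (length(attained) != 2L) next
    }
    keep[i] <- TRUE
    clade_allele[i] <- a
    out_alleles[i] <- paste(sort(unique(rownames(other)[apply(other, 1, any)])),
                            collapse = ",")
    freq_rows[[length(freq_rows) + 1L]] <-
      sweep(vs$ar[[i]][a, vs$samples, drop = FALSE], 2, vs$dp[i, vs$samples], "/")[1, ]
  }
  idx <- which(keep)
  ord <- idx[order(vs$sites$chrom[idx], vs$sites$pos[idx])]
  res <- data.frame(vs$sites[ord, c("chrom", "pos", "ref", "alts")],
                    clade_allele = clade_allele[ord],
                    out_alleles = out_alleles[ord],
                    stringsAsFactors = FALSE)
  fm <- if (length(idx) > 0) {
    do.call(rbind, freq_rows)[match(ord, idx), , drop = FALSE]
  } else {
    matrix(numeric(0), 0, length(vs$samples))
  }
  colnames(fm) <- vs$samples
  rownames(res) <- NULL
  structure(res, per_sample_freq = fm, class = c("clade_calls", "data.frame"))
}

#' Write clade-specific calls as a TSV report
#' @param calls A `clade_calls` object.
#' @param path Output file.
#' @export
write_clade_calls <- function(calls, path) {
  fm <- attr(calls, "per_sample_freq")
  df <- as.data.frame(calls)
  if (!is.null(fm) && ncol(fm) > 0) {
    freqs <- as.data.frame(round(fm, 4))
    names(freqs) <- paste0("freq_", colnames(fm))
    df <- cbind(df, freqs)
  }
  write_tsv_commented(df, path)
}

#' Count distinct genomic loci among clade-specific calls
#'
#' Maps every call to exactly one locus: the gene owning its primary effect,
#' or, for intergenic calls, an identifier for the interval between the two
#' flanking genes.
#'
#' @param calls A `clade_calls` object.
#' @param genes A `gene_models` object.
#' @param genome Genome list (needed for coding classification).
#' @return List with `n_loci` (distinct locus count) and `loci` (data frame
#'   call -> `locus_id`).
#' @export
summarize_loci <- function(calls, genes, genome) {
  eff <- annotate_calls(calls, genes, genome)
  locus <- eff$gene_id
  inter <- is.na(locus)
  if (any(inter)) {
    locus[inter] <- vapply(which(inter), function(k) {
      intergenic_interval_id(eff$chrom[k], eff$pos[k], genes)
    }, character(1))
  }
  list(n_loci = length(unique(locus)),
       loci = data.frame(chrom = eff$chrom, pos = eff$pos, locus_id = locus,
                         stringsAsFactors = FALSE))
}

# Identifier of the inter-gene interval containing pos on chrom.
intergenic_interval_id <- function(chrom, pos, genes) {
  on_chrom <- Filter(function(g) g$chrom == chrom, genes)
  if (length(on_chrom) == 0) return(sprintf("intergenic:%s:0", chrom))
  starts <- sort(vapply(on_chrom, `[[`, numeric(1), "start"))
  k <- findInterval(pos, starts)
  sprintf("intergenic:%s:%d", chrom, k)
}
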