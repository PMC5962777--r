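# SNP-matrix phylogeny: site selection by the major-allele rules,
# concatenation to pseudo-sequences, p-distances, and Saitou–Nei neighbor
# joining with a deterministic tie rule.

#' Select sites for tree building into a major-allele matrix
#'
#' A site is retained iff, in every sample, the major allele (highest read
#' frequency; ties broken by lexicographically smallest allele) reaches
#' frequency >= `min_freq` at depth >= `min_depth`, and at least two distinct
#' major alleles occur across samples (sites where all samples share the
#' major allele carry no tree signal and are excluded).
#'
#' @param vs A [variant_set()].
#' @param min_freq Major-allele frequency bound (default 0.9).
#' @param min_depth Depth bound (default 20).
#' @param snps_only If `TRUE` (default), sites with any non-single-base
#'   allele are dropped; if `FALSE`, indel alleles are encoded as `-` in the
#'   pseudo-sequences.
#' @return Object of class `snp_matrix`: list with `samples`, `sites` (data
#'   frame `chrom`, `pos`, in genomic order) and `alleles` (sites x samples
#'   character matrix).
#' @export
select_tree_sites <- function(vs, min_freq = 0.9, min_depth = 20, snps_only = TRUE) {
  stopifnot(inherits(vs, "variant_set"))
  if (length(vs$samples) < 2) flv_stop("tree site selection needs >= 2 samples")
  keep <- logical(n_sites(vs))
  majors <- vector("list", n_sites(vs))
  for (i in seq_len(n_sites(vs))) {
    alleles <- rownames(vs$ar[[i]])
    if (snps_only && any(nchar(alleles) != 1L)) next
    dp <- vs$dp[i, ]
    if (anyNA(dp) || any(dp < min_depth)) next
    fr <- sweep(vs$ar[[i]], 2, dp, "/")
    mj <- apply(fr, 2, function(col) {
      top <- which(col == max(col))
      alleles[top[order(alleles[top])[1]]]
    })
    mf <- fr[cbind(match(mj, alleles), seq_along(mj))]
    if (any(mf < min_freq)) next
    if (length(unique(mj)) < 2) next
    keep[i] <- TRUE
    majors[[i]] <- mj
  }
  idx <- which(keep)
  idx <- idx[order(vs$sites$chrom[idx], vs$sites$pos[idx])]
  am <- if (length(idx) > 0) {
    do.call(rbind, majors[idx])
  } else {
    matrix(character(0), 0, length(vs$samples))
  }
  colnames(am) <- vs$samples
  structure(list(samples = vs$samples,
                 sites = vs$sites[idx, c("chrom", "pos"), drop = FALSE],
                 alleles = am),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d sites x %d samples\n", nrow(x$alleles), length(x$samples)))
  invisible(x)
}

#' Concatenate a SNP matrix into per-sample pseudo-sequences
#'
#' Column j of each sequence is the sample's major allele at site j; alleles
#' longer or shorter than one base are encoded as `-`.
#'
#' @param matrix A `snp_matrix` (non-empty).
#' @param fasta_path Optional path; when given, the pseudo-alignment is also
#'   written as FASTA (e.g. as input to an external ML tree program).
#' @return Named character vector sample -> sequence.
#' @export
concatenate_snp_matrix <- function(matrix, fasta_path = NULL) {
  stopifnot(inherits(matrix, "snp_matrix"))
  if (nrow(matrix$alleles) == 0) flv_stop("cannot concatenate an empty SNP matrix")
  am <- matrix$alleles
  am[nchar(am) != 1L] <- "-"
  seqs <- apply(am, 2, paste, collapse = "")
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(gsub("[^ACGT]", "N", seqs))
    names(ss) <- names(seqs)
    Biostrings::writeXStringSet(ss, fasta_path, width = 70)
    return(invisible(seqs))
  }
  seqs
}

#' Pairwise p-distances between SNP matrix rows
#'
#' @param matrix A `snp_matrix`.
#' @return Symmetric matrix of mismatch proportions (mismatched columns /
#'   total columns); indel-encoded alleles count as mismatches against
#'   anything they differ from.
#' @export
p_distance <- function(matrix) {
  stopifnot(inherits(matrix, "snp_matrix"))
  am <- matrix$alleles
  ns <- length(matrix$samples)
  if (nrow(am) == 0) flv_stop("p-distance undefined for an empty SNP matrix")
  d <- base::matrix(0, ns, ns, dimnames = list(matrix$samples, matrix$samples))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      d[i, j] <- d[j, i] <- mean(am[, i] != am[, j])
    }
  }
  d
}

quote_newick_label <- function(x) {
  needs <- grepl("[][(),:;'\" \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei agglomeration with a deterministic tie rule: at each
#' step the pair with the smallest Q criterion is joined, ties broken by the
#' lexicographically smallest (label, label) pair, where a cluster is
#' labelled by its smallest member taxon. Negative branch lengths are clamped
#' to zero. The result is an unrooted tree (trifurcating root node).
#'
#' @param d Symmetric numeric distance matrix with taxon dimnames, n >= 3.
#' @return An \pkg{ape} `phylo` tree whose leaves are the taxa of `d`.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) flv_stop("d must be a square matrix")
  n <- nrow(d)
  if (n < 3) flv_stop("neighbor joining needs >= 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-9) flv_stop("distance matrix must be symmetric")
  D <- d
  nwk <- quote_newick_label(labs)   # growing newick substring per cluster
  tie <- labs                        # smallest member taxon per cluster
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pair_lab <- apply(best, 1, function(ij) {
      paste(sort(c(tie[ij[1]], tie[ij[2]])), collapse = "\r")
    })
    pick <- best[order(pair_lab)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_tie <- min(tie[i], tie[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    tie <- c(tie[keep], new_tie)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt(la), nwk[2], fmt(lb), nwk[3], fmt(lc))
  ape::read.tree(text = text)
}

#' Are the given taxa monophyletic in an unrooted tree?
#'
#' True iff some edge of the tree bipartitions the leaf set into exactly
#' `taxa` vs the rest (checked by rooting at an outside taxon).
#'
#' @param tree An ape `phylo`.
#' @param taxa Character vector of leaf labels.
#' @return Logical.
#' @export
is_clade_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  rest <- setdiff(tree$tip.label, taxa)
  if (length(rest) == 0 || length(taxa) == 0) return(TRUE)
  if (!all(taxa %in% tree$tip.label)) flv_stop("taxa absent from tree")
  rooted <- ape::root(tree, outgroup = rest[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}
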