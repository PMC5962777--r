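# Readers and writers for the external formats the pipeline touches.
#
# Coordinate convention: everything in this package is 1-based inclusive, the
# native convention of VCF and GFF3; no conversion happens anywhere.

## ---- sample groups -----------------------------------------------------

#' Two-clade sample grouping
#'
#' Assigns each sample to one of two clades (e.g. flor vs wine) and designates
#' which label is the "in" clade whose fixed alleles the discrimination filter
#' looks for.
#'
#' @param groups Named character vector: sample id -> group label. Exactly two
#'   distinct labels must be present.
#' @param in_clade Label of the in-clade (default `"flor"`).
#' @return An object of class `group_config` with elements `groups`,
#'   `in_clade_label`, `out_clade_label`.
#' @export
group_config <- function(groups, in_clade = "flor") {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    flv_stop("groups must be a named character vector (sample -> label)")
  }
  if (anyDuplicated(names(groups))) {
    flv_stop("duplicated sample id in group config: %s",
             paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  }
  labs <- unique(unname(groups))
  if (length(labs) != 2L) {
    flv_stop("group config must contain exactly 2 group labels, found %d (%s)",
             length(labs), paste(labs, collapse = ", "))
  }
  if (!in_clade %in% labs) {
    flv_stop("in-clade label '%s' not present in group file (labels: %s)",
             in_clade, paste(labs, collapse = ", "))
  }
  out <- setdiff(labs, in_clade)
  structure(
    list(groups = groups, in_clade_label = in_clade, out_clade_label = out),
    class = "group_config"
  )
}

#' @export
print.group_config <- function(x, ...) {
  cat(sprintf("group_config: %d in-clade ('%s') / %d out-clade ('%s') samples\n",
              sum(x$groups == x$in_clade_label), x$in_clade_label,
              sum(x$groups == x$out_clade_label), x$out_clade_label))
  invisible(x)
}

in_samples <- function(groups) names(groups$groups)[groups$groups == groups$in_clade_label]
out_samples <- function(groups) names(groups$groups)[groups$groups == groups$out_clade_label]

#' Read a two-column sample-group file
#'
#' @param path TSV with columns `sample_id`, `group` (commented header allowed).
#' @param in_clade In-clade label, see [group_config()].
#' @return A `group_config`.
#' @export
read_groups <- function(path, in_clade = "flor") {
  df <- read_tsv_commented(path, col.names = c("sample_id", "group"),
                           colClasses = c("character", "character"))
  group_config(stats::setNames(df$group, df$sample_id), in_clade = in_clade)
}

#' Write a sample-group file
#' @param groups A `group_config`.
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  write_tsv_commented(
    data.frame(sample_id = names(groups$groups), group = unname(groups$groups),
               stringsAsFactors = FALSE),
    path
  )
}

## ---- variant sets ------------------------------------------------------

#' Construct a multi-sample variant set
#'
#' The internal container for multi-sample variant calls: one row per site with
#' per-sample read depth and per-allele read counts (the freebayes DP/RO/AO
#' quantities). A sample with no data at a site carries depth `NA` ("no-data"),
#' which downstream filters treat as failing, distinct from depth 0.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alts` (comma-joined alternate alleles).
#' @param samples Character vector of sample ids (column order of matrices).
#' @param dp Numeric matrix `nrow(sites) x length(samples)` of depths; `NA`
#'   means no data.
#' @param ar List of length `nrow(sites)`; element i is a numeric matrix
#'   alleles x samples of read counts, rownames `c(ref, alt1, ...)`.
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(sites, samples, dp, ar) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alts") %in% names(sites)))
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) flv_stop("variant pos must be >= 1")
    if (any(!nzchar(sites$ref))) flv_stop("empty ref allele")
    if (any(!nzchar(sites$alts))) flv_stop("site without alternate allele")
    bad <- mapply(function(r, a) r %in% strsplit(a, ",", fixed = TRUE)[[1]],
                  sites$ref, sites$alts)
    if (any(bad)) flv_stop("alt allele identical to ref at row %d", which(bad)[1])
  }
  if (!identical(dim(dp), c(nrow(sites), length(samples)))) {
    flv_stop("dp matrix must be n_sites x n_samples")
  }
  if (length(ar) != nrow(sites)) flv_stop("ar list length must equal site count")
  colnames(dp) <- samples
  structure(list(sites = sites, samples = samples, dp = dp, ar = ar),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples\n", nrow(x$sites), length(x$samples)))
  invisible(x)
}

n_sites <- function(vs) nrow(vs$sites)

site_alleles <- function(vs, i) {
  c(vs$sites$ref[i], strsplit(vs$sites$alts[i], ",", fixed = TRUE)[[1]])
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses VCF v4.2 through \pkg{vcfR}. Per-sample observations are taken from
#' the freebayes-dialect `DP`/`RO`/`AO` FORMAT fields; when `RO`/`AO` are
#' absent the GATK-style `AD` field is used instead. Samples with a missing
#' genotype/depth at a site are marked no-data (`NA` depth).
#'
#' @param path VCF file.
#' @param groups Optional `group_config`; if given, every grouped sample must
#'   appear in the VCF header.
#' @return A [variant_set()].
#' @export
read_variants <- function(path, groups = NULL) {
  if (!file.exists(path)) flv_stop("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (!is.null(groups)) {
    missing <- setdiff(names(groups$groups), samples)
    if (length(missing) > 0) {
      flv_stop("samples in group config absent from VCF header: %s",
               paste(missing, collapse = ", "))
    }
  }
  nrec <- nrow(vcf@fix)
  if (is.null(nrec) || nrec == 0L) {
    return(variant_set(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alts = character(0), stringsAsFactors = FALSE),
      samples,
      matrix(numeric(0), 0, length(samples)),
      list()
    ))
  }
  fix <- vcf@fix
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) flv_stop("malformed POS at VCF record %d", which(is.na(pos))[1])
  sites <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                      ref = fix[, "REF"], alts = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  has_roao <- all(vapply(fmt, function(f) all(c("RO", "AO") %in% f), logical(1)))
  has_ad <- all(vapply(fmt, function(f) "AD" %in% f, logical(1)))
  if (!has_roao && !has_ad) {
    flv_stop("VCF FORMAT must carry RO/AO (freebayes) or AD allele counts")
  }
  dp_chr <- vcfR::extract.gt(vcf, element = "DP")
  dp <- suppressWarnings(apply(dp_chr, 2, as.numeric))
  dp <- matrix(dp, nrow = nrec, dimnames = dimnames(dp_chr))
  split_counts <- function(x) {
    if (is.na(x) || x == ".") return(NULL)
    suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  }
  if (has_roao) {
    ro <- vcfR::extract.gt(vcf, element = "RO")
    ao <- vcfR::extract.gt(vcf, element = "AO")
  } else {
    ad <- vcfR::extract.gt(vcf, element = "AD")
  }
  ar <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    alleles <- c(sites$ref[i], strsplit(sites$alts[i], ",", fixed = TRUE)[[1]])
    m <- matrix(NA_real_, length(alleles), length(samples),
                dimnames = list(alleles, samples))
    for (s in seq_along(samples)) {
      counts <- if (has_roao) {
        r <- split_counts(ro[i, s]); a <- split_counts(ao[i, s])
        if (is.null(r) || is.null(a)) NULL else c(r, a)
      } else {
        split_counts(ad[i, s])
      }
      if (!is.null(counts)) {
        if (length(counts) != length(alleles)) {
          flv_stop("allele count arity mismatch at VCF record %d, sample %s", i, samples[s])
        }
        m[, s] <- counts
      }
    }
    ar[[i]] <- m
  }
  # a sample without usable counts is no-data regardless of DP
  nodata <- t(vapply(ar, function(m) apply(m, 2, function(col) anyNA(col)), logical(length(samples))))
  if (length(samples) == 1L) nodata <- matrix(nodata, ncol = 1L)
  dp[nodata] <- NA_real_
  variant_set(sites, samples, dp, ar)
}

#' Write a variant set as a freebayes-dialect VCF
#'
#' Emits VCF v4.2 with FORMAT `GT:DP:RO:AO`. Genotypes are summarised from the
#' read counts (homozygous call at >= 90% frequency, else heterozygous).
#'
#' @param vs A [variant_set()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=florvar",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            vs$samples), collapse = "\t")
  )
  writeLines(hdr, con)
  for (i in seq_len(n_sites(vs))) {
    m <- vs$ar[[i]]
    cells <- vapply(seq_along(vs$samples), function(s) {
      d <- vs$dp[i, s]
      if (is.na(d) || anyNA(m[, s])) return("./.:.:.:.")
      counts <- m[, s]
      fr <- if (d > 0) counts / d else counts * 0
      top <- which.max(fr)
      gt <- if (fr[top] >= 0.9) {
        paste(top - 1L, top - 1L, sep = "/")
      } else {
        o <- order(fr, decreasing = TRUE)[1:2] - 1L
        paste(sort(o), collapse = "/")
      }
      sprintf("%s:%d:%d:%s", gt, as.integer(d), as.integer(counts[1]),
              paste(as.integer(counts[-1]), collapse = ","))
    }, character(1))
    writeLines(paste(c(vs$sites$chrom[i], vs$sites$pos[i], ".", vs$sites$ref[i],
                       vs$sites$alts[i], ".", "PASS",
                       sprintf("DP=%d", as.integer(sum(vs$dp[i, ], na.rm = TRUE))),
                       "GT:DP:RO:AO", cells), collapse = "\t"), con)
  }
  invisible(path)
}

## ---- gene models -------------------------------------------------------

gene_model <- function(gene_id, chrom, strand, cds, upstream_window, downstream_window) {
  stopifnot(strand %in% c("+", "-"))
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(cds[, 2] < cds[, 1])) flv_stop("zero/negative-length CDS interval in %s", gene_id)
  if (nrow(cds) > 1) {
    if (any(cds[-1, 1] <= cds[-nrow(cds), 2])) {
      flv_stop("overlapping CDS intervals in gene %s", gene_id)
    }
  }
  introns <- NULL
  if (nrow(cds) > 1) {
    introns <- cbind(start = cds[-nrow(cds), 2] + 1, end = cds[-1, 1] - 1)
  } else {
    introns <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       cds = cds, introns = introns,
       start = min(cds[, 1]), end = max(cds[, 2]),
       upstream_window = upstream_window, downstream_window = downstream_window)
}

# Promoter / terminator windows in genome coordinates, clipped at 1.
gene_upstream_interval <- function(gene) {
  w <- gene$upstream_window
  if (w <= 0) return(c(NA_real_, NA_real_))
  if (gene$strand == "+") c(max(1, gene$start - w), gene$start - 1)
  else c(gene$end + 1, gene$end + w)
}

gene_downstream_interval <- function(gene) {
  w <- gene$downstream_window
  if (w <= 0) return(c(NA_real_, NA_real_))
  if (gene$strand == "+") c(gene$end + 1, gene$end + w)
  else c(max(1, gene$start - w), gene$start - 1)
}

#' Read gene models from GFF3
#'
#' Groups CDS features under their parent gene, derives introns as the gaps
#' between consecutive CDS intervals, and attaches promoter (upstream) and
#' terminator (downstream) windows used by the effect classifier. The GFF3
#' phase column is ignored; reading frame follows from CDS interval order and
#' strand.
#'
#' @param path GFF3 file with `gene` and `CDS` features (1-based inclusive).
#' @param upstream_window,downstream_window Window sizes in bp (default 1000).
#' @return Object of class `gene_models`: a list of gene records.
#' @export
read_gene_models <- function(path, upstream_window = 1000, downstream_window = 1000) {
  if (!file.exists(path)) flv_stop("GFF3 not found: %s", path)
  if (upstream_window < 0 || downstream_window < 0) flv_stop("windows must be >= 0")
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) > 0) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L)) {
      flv_stop("%s line %d: expected 9 GFF3 columns, found %d",
               path, which(nf != 9L)[1], nf[nf != 9L][1])
    }
    st <- as.numeric(vapply(fields, `[`, "", 4L))
    en <- as.numeric(vapply(fields, `[`, "", 5L))
    if (any(en < st)) {
      flv_stop("%s line %d: zero-length interval (end < start)", path, which(en < st)[1])
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gidx <- which(typ == "gene")
  cidx <- which(typ == "CDS")
  gene_ids <- as.character(gr$ID[gidx])
  parent_of <- vapply(gr$Parent[cidx], function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  if (anyNA(parent_of)) flv_stop("CDS feature without Parent attribute in %s", path)
  orphan <- setdiff(unique(parent_of), gene_ids)
  if (length(orphan) > 0) {
    flv_stop("CDS with parent not declared as gene: %s", paste(orphan, collapse = ", "))
  }
  genes <- lapply(seq_along(gidx), function(k) {
    gid <- gene_ids[k]
    mine <- cidx[parent_of == gid]
    if (length(mine) == 0) flv_stop("gene %s has no CDS feature", gid)
    cds <- cbind(start = BiocGenerics::start(gr)[mine], end = BiocGenerics::end(gr)[mine])
    gene_model(gid, as.character(GenomicRanges::seqnames(gr))[gidx[k]],
               as.character(BiocGenerics::strand(gr))[gidx[k]],
               cds, upstream_window, downstream_window)
  })
  names(genes) <- gene_ids
  structure(genes[order(vapply(genes, `[[`, numeric(1), "start"))], class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %s\n", length(x),
              paste(unique(vapply(x, `[[`, "", "chrom")), collapse = ",")))
  invisible(x)
}

#' Write gene models as GFF3
#' @param genes A `gene_models` object (or plain list of gene records).
#' @param path Output file.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(sprintf("%s\tflorvar\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    for (k in seq_len(nrow(g$cds))) {
      writeLines(sprintf("%s\tflorvar\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                         g$chrom, g$cds[k, 1], g$cds[k, 2], g$strand,
                         g$gene_id, k, g$gene_id), con)
    }
  }
  invisible(path)
}

## ---- genome FASTA ------------------------------------------------------

#' Read a genome FASTA into a named list of chromosome strings
#' @param path FASTA file.
#' @return Named list chrom -> sequence string (uppercase).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.list(toupper(as.character(ss)))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome (named list of strings) as FASTA
#' @param genome Named list chrom -> sequence string.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

## ---- coverage / hits tables -------------------------------------------

#' Read a per-gene breadth-of-coverage table
#'
#' @param path TSV with columns `gene_id`, `sample`, `covered_fraction`.
#' @return Data frame with those columns; fractions validated to `[0, 1]`,
#'   duplicate (gene, sample) keys rejected.
#' @export
read_coverage <- function(path) {
  df <- read_tsv_commented(path, col.names = c("gene_id", "sample", "covered_fraction"),
                           colClasses = c("character", "character", "numeric"))
  if (anyNA(df$covered_fraction)) flv_stop("%s: non-numeric covered_fraction", path)
  if (any(df$covered_fraction < 0 | df$covered_fraction > 1)) {
    flv_stop("%s: covered_fraction outside [0,1]", path)
  }
  key <- paste(df$gene_id, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    flv_stop("%s: duplicated (gene_id, sample) key: %s", path,
             sub("\r", "/", key[duplicated(key)][1]))
  }
  df
}

#' Read a 12-column BLAST tabular (outfmt 6) hit table
#'
#' @param path TSV in the standard outfmt-6 column layout.
#' @return Data frame with columns `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `evalue`, `bit_score`.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  df <- read_tsv_commented(path, col.names = cols,
                           colClasses = c("character", "character", rep("numeric", 10)))
  if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
    flv_stop("%s: percent identity outside [0,100]", path)
  }
  if (any(df$alignment_length < 0)) flv_stop("%s: negative alignment length", path)
  df
}

## ---- newick ------------------------------------------------------------

#' Write a phylogenetic tree to a newick file
#'
#' @param tree An \pkg{ape} `phylo` object.
#' @param path Output file; the serialisation terminates with `";"` and quotes
#'   labels containing newick-reserved characters.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
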