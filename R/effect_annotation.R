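# Variant effect classification against gene models, Table-style category
# tabulation, and the count-based dN/dS ratio.
#
# Coding single-nucleotide and equal-length multi-nucleotide substitutions are
# classified by strand-aware codon translation under the standard nuclear
# genetic code; CDS indels by reading-frame arithmetic; everything else by
# window geometry. Severity precedence (most severe first):
# frameshift > stop_splice > missense > synonymous > intron > upstream >
# downstream > intergenic.

# Genomic positions of a gene's CDS in translation (5'->3') order, with the
# template bases already strand-adjusted.
cds_map <- function(gene, genome) {
  gpos <- unlist(lapply(seq_len(nrow(gene$cds)), function(k) {
    seq(gene$cds[k, 1], gene$cds[k, 2])
  }), use.names = FALSE)
  bases <- genome_bases(genome, gene$chrom, gpos)
  if (gene$strand == "-") {
    gpos <- rev(gpos)
    bases <- dna_complement(rev(bases))
  }
  list(gpos = gpos, bases = toupper(bases))
}

# Classify an equal-length substitution against one gene's CDS by translating
# only the affected codons. Returns list(category, detail) or NULL when no
# coding base actually changes.
classify_coding_substitution <- function(gene, genome, pos, ref, alt) {
  map <- cds_map(gene, genome)
  refv <- strsplit(toupper(ref), "", fixed = TRUE)[[1]]
  altv <- strsplit(toupper(alt), "", fixed = TRUE)[[1]]
  gpos_var <- pos + seq_along(refv) - 1L
  changed <- refv != altv
  j <- match(gpos_var[changed], map$gpos)
  newbase <- altv[changed]
  inside <- !is.na(j)
  if (!any(inside)) return(NULL)
  j <- j[inside]
  newbase <- newbase[inside]
  if (gene$strand == "-") newbase <- dna_complement(newbase)
  mut <- map$bases
  mut[j] <- toupper(newbase)
  codons <- sort(unique((j - 1L) %/% 3L))
  old_aa <- new_aa <- character(0)
  old_cod <- new_cod <- character(0)
  for (ci in codons) {
    span <- (ci * 3L + 1L):(ci * 3L + 3L)
    if (max(span) > length(map$bases)) next   # incomplete trailing codon: skip
    oc <- paste(map$bases[span], collapse = "")
    nc <- paste(mut[span], collapse = "")
    old_cod <- c(old_cod, oc); new_cod <- c(new_cod, nc)
    old_aa <- c(old_aa, codon_aa(oc)); new_aa <- c(new_aa, codon_aa(nc))
  }
  if (length(old_aa) == 0) return(NULL)
  detail_codons <- paste(sprintf("%s>%s", old_cod, new_cod), collapse = ",")
  if (all(old_aa == new_aa)) {
    list(category = "synonymous", detail = detail_codons)
  } else if (any(new_aa == "*" & old_aa != "*")) {
    list(category = "stop_splice", detail = paste0("stop_gained:", detail_codons))
  } else if (any(old_aa == "*" & new_aa != "*")) {
    list(category = "stop_splice", detail = paste0("stop_lost:", detail_codons))
  } else {
    list(category = "missense",
         detail = sprintf("%s(%s>%s)", detail_codons,
                          paste(old_aa, collapse = ""), paste(new_aa, collapse = "")))
  }
}

span_overlaps <- function(s1, e1, s2, e2) s1 <= e2 && e1 >= s2

#' Classify one variant against all gene models
#'
#' Produces one effect record per overlapped feature region: coding (by codon
#' translation), intron/splice-region (splice = first or last 2 nt of an
#' intron), promoter (upstream window) or terminator (downstream window). A
#' variant overlapping nothing yields a single intergenic record with
#' `gene_id = NA`.
#'
#' @param chrom,pos,ref,alt The variant (VCF-style, 1-based; indels anchored).
#' @param genes A `gene_models` object.
#' @param genome Genome list as from [read_genome()].
#' @param check_ref If `TRUE` (default), error when `ref` disagrees with the
#'   genome sequence at `pos`.
#' @return Data frame of records: `gene_id`, `category`, `detail`.
#' @export
classify_variant <- function(chrom, pos, ref, alt, genes, genome, check_ref = TRUE) {
  if (!chrom %in% names(genome)) {
    flv_stop("variant chromosome '%s' absent from genome", chrom)
  }
  ref <- toupper(ref); alt <- toupper(alt)
  if (check_ref) {
    gref <- toupper(genome_substr(genome, chrom, pos, pos + nchar(ref) - 1L))
    if (gref != ref) {
      flv_stop("ref allele mismatch at %s:%d: VCF says %s, genome has %s",
               chrom, pos, ref, gref)
    }
  }
  is_indel <- nchar(ref) != nchar(alt)
  span <- c(pos, pos + nchar(ref) - 1L)
  recs <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    rec <- NULL
    cds_hit <- any(vapply(seq_len(nrow(g$cds)), function(k) {
      span_overlaps(span[1], span[2], g$cds[k, 1], g$cds[k, 2])
    }, logical(1)))
    if (cds_hit) {
      if (is_indel) {
        shift <- abs(nchar(ref) - nchar(alt)) %% 3L
        rec <- if (shift != 0L) {
          list(category = "frameshift", detail = sprintf("indel_%+d", nchar(alt) - nchar(ref)))
        } else {
          list(category = "missense", detail = "inframe_indel")
        }
      } else {
        rec <- classify_coding_substitution(g, genome, pos, ref, alt)
      }
    }
    if (is.null(rec) && nrow(g$introns) > 0) {
      for (k in seq_len(nrow(g$introns))) {
        is_ <- g$introns[k, 1]; ie <- g$introns[k, 2]
        if (!span_overlaps(span[1], span[2], is_, ie)) next
        splice <- span_overlaps(span[1], span[2], is_, min(is_ + 1, ie)) ||
          span_overlaps(span[1], span[2], max(ie - 1, is_), ie)
        rec <- if (splice) {
          list(category = "stop_splice", detail = "splice_region")
        } else {
          list(category = "intron", detail = sprintf("intron_%d", k))
        }
        break
      }
    }
    if (is.null(rec)) {
      up <- gene_upstream_interval(g)
      if (!anyNA(up) && up[1] <= up[2] && span_overlaps(span[1], span[2], up[1], up[2])) {
        rec <- list(category = "upstream",
                    detail = sprintf("dist_%d", if (g$strand == "+") g$start - span[2] else span[1] - g$end))
      }
    }
    if (is.null(rec)) {
      dn <- gene_downstream_interval(g)
      if (!anyNA(dn) && dn[1] <= dn[2] && span_overlaps(span[1], span[2], dn[1], dn[2])) {
        rec <- list(category = "downstream",
                    detail = sprintf("dist_%d", if (g$strand == "+") span[1] - g$end else g$start - span[2]))
      }
    }
    if (!is.null(rec)) {
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = g$gene_id, category = rec$category, detail = rec$detail,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0) {
    return(data.frame(gene_id = NA_character_, category = "intergenic",
                      detail = "", stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Reduce a variant's effect records to its primary record
#'
#' Picks the single most severe record by the category precedence
#' frameshift > stop_splice > missense > synonymous > intron > upstream >
#' downstream > intergenic; ties at equal severity are broken by the
#' lexicographically smallest `gene_id`.
#'
#' @param records Data frame as returned by [classify_variant()] (>= 1 row).
#' @return One-row data frame.
#' @export
primary_category <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    flv_stop("primary_category() requires at least one effect record")
  }
  prio <- match(records$category, CATEGORY_LEVELS)
  if (anyNA(prio)) {
    flv_stop("unknown effect category: %s", records$category[is.na(prio)][1])
  }
  tie_gene <- ifelse(is.na(records$gene_id), "\uffff", records$gene_id)
  records[order(prio, tie_gene)[1], , drop = FALSE]
}

#' Annotate clade-specific calls with their primary effect
#'
#' The allele classified at each site is the non-reference allele of interest:
#' the clade-fixed allele when it differs from the reference, otherwise the
#' (out-clade) alternate allele — the site's variation relative to the
#' reference genome either way.
#'
#' @param calls A `clade_calls` data frame (or any data frame with `chrom`,
#'   `pos`, `ref`, `alts`, `clade_allele`).
#' @param genes A `gene_models` object.
#' @param genome Genome list.
#' @param check_ref Passed to [classify_variant()].
#' @return Data frame with one row per call: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `category`, `detail`.
#' @export
annotate_calls <- function(calls, genes, genome, check_ref = TRUE) {
  n <- nrow(calls)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(calls$alts[i], ",", fixed = TRUE)[[1]]
    alt <- if (!is.null(calls$clade_allele) && calls$clade_allele[i] != calls$ref[i]) {
      calls$clade_allele[i]
    } else {
      alts[1]
    }
    rec <- primary_category(
      classify_variant(calls$chrom[i], calls$pos[i], calls$ref[i], alt,
                       genes, genome, check_ref = check_ref)
    )
    out[[i]] <- data.frame(chrom = calls$chrom[i], pos = calls$pos[i],
                           ref = calls$ref[i], alt = alt,
                           gene_id = rec$gene_id, category = rec$category,
                           detail = rec$detail, stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), gene_id = character(0),
                      category = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tabulate primary effect records into a category table
#'
#' @param effects Data frame of primary effect records (one per variant) with
#'   a `category` column.
#' @return Object of class `category_table`: named integer vector over all
#'   eight categories plus attribute `total`. Counts always partition the
#'   input: `sum(counts) == nrow(effects)`.
#' @export
tabulate_categories <- function(effects) {
  cat_f <- factor(effects$category, levels = CATEGORY_LEVELS)
  if (anyNA(cat_f) && nrow(effects) > 0) {
    flv_stop("unknown effect category: %s", effects$category[is.na(cat_f)][1])
  }
  counts <- table(cat_f)
  out <- stats::setNames(as.integer(counts), names(counts))
  structure(out, total = sum(out), class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  for (nm in names(unclass(x))) cat(sprintf("%-12s %d\n", nm, x[[nm]]))
  cat(sprintf("%-12s %d\n", "total", attr(x, "total")))
  invisible(x)
}

#' Count-based dN/dS ratio
#'
#' The ratio of missense to synonymous variant counts in coding regions — a
#' raw count ratio, not a site-normalised (Nei–Gojobori-style) estimator.
#' Values above 1 are read as a signal of positive selection.
#'
#' @param x A `category_table`, or anything with named entries `missense` and
#'   `synonymous`, or a numeric vector `c(missense, synonymous)`.
#' @return `missense / synonymous`; `Inf` flags missense with zero synonymous
#'   counts, `NaN` flags the ratio being undefined (both zero).
#' @export
dn_ds <- function(x) {
  if (!is.null(names(x)) && all(c("missense", "synonymous") %in% names(x))) {
    m <- as.numeric(x[["missense"]]); s <- as.numeric(x[["synonymous"]])
  } else if (is.numeric(x) && length(x) == 2) {
    m <- x[1]; s <- x[2]
  } else {
    flv_stop("dn_ds() needs missense and synonymous counts")
  }
  if (m < 0 || s < 0) flv_stop("negative category count")
  m / s
}
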