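# Coverage-threshold gene presence/absence and hit-table novelty detection.
#
# "Coverage" throughout means breadth: the fraction of a gene's bases covered
# by at least one read, not mean depth. A gene is missing when breadth falls
# strictly below 50%; a candidate gene is novel when no alignment reaches
# strictly more than 70% identity over strictly more than 80% of its length.

#' Breadth of coverage of a gene from per-base coverage intervals
#'
#' @param intervals Data frame with columns `start`, `end` (1-based inclusive,
#'   depth >= 1 regions); must lie within the gene span.
#' @param gene A gene record (from `gene_models`); the span is
#'   `gene$start..gene$end`.
#' @return Fraction of gene bases covered, in `[0, 1]`. Overlapping intervals
#'   are unioned before counting.
#' @export
coverage_fraction <- function(intervals, gene) {
  glen <- gene$end - gene$start + 1
  if (nrow(intervals) == 0) return(0)
  if (any(intervals$start < gene$start | intervals$end > gene$end)) {
    flv_stop("coverage interval outside gene %s span [%d, %d]",
             gene$gene_id, gene$start, gene$end)
  }
  if (any(intervals$end < intervals$start)) flv_stop("interval with end < start")
  iv <- intervals[order(intervals$start), , drop = FALSE]
  covered <- 0
  cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start[k] <= cur_e + 1) {
      cur_e <- max(cur_e, iv$end[k])
    } else {
      covered <- covered + (cur_e - cur_s + 1)
      cur_s <- iv$start[k]; cur_e <- iv$end[k]
    }
  }
  covered <- covered + (cur_e - cur_s + 1)
  covered / glen
}

#' Call missing genes from breadth-of-coverage fractions
#'
#' @param fractions Named numeric vector gene -> covered fraction.
#' @param threshold A gene is missing iff its fraction is strictly below this
#'   value (default 0.5, i.e. "less than 50%").
#' @param confirm_fractions Optional second evidence track (e.g. breadth of
#'   coverage by de novo assembly contigs rather than reads): when supplied, a
#'   gene is only called missing if it falls below the threshold in both
#'   tracks.
#' @return Sorted character vector of missing gene ids.
#' @export
call_missing <- function(fractions, threshold = 0.5, confirm_fractions = NULL) {
  if (any(fractions < 0 | fractions > 1)) flv_stop("coverage fraction outside [0,1]")
  missing <- names(fractions)[fractions < threshold]
  if (!is.null(confirm_fractions)) {
    if (any(confirm_fractions < 0 | confirm_fractions > 1)) {
      flv_stop("coverage fraction outside [0,1]")
    }
    missing <- intersect(missing,
                         names(confirm_fractions)[confirm_fractions < threshold])
  }
  sort(missing)
}

#' Missing genes shared by all strains vs exclusive to single strains
#'
#' @param per_strain Named list strain -> character vector of missing genes.
#' @return List with `shared` (missing in every strain) and `exclusive`
#'   (per strain, genes missing there and in no other strain).
#' @export
shared_missing <- function(per_strain) {
  if (length(per_strain) < 2) flv_stop("shared_missing() needs >= 2 strains")
  shared <- sort(Reduce(intersect, per_strain))
  exclusive <- lapply(seq_along(per_strain), function(i) {
    others <- unique(unlist(per_strain[-i]))
    sort(setdiff(per_strain[[i]], others))
  })
  names(exclusive) <- names(per_strain)
  list(shared = shared, exclusive = exclusive)
}

#' Detect novel (non-reference) genes from a BLAST tabular hit table
#'
#' A candidate is novel iff it has no hit with `percent_identity > 70` AND
#' `alignment_length / query_length > 0.8` (both strict, per "more than").
#'
#' @param hits Data frame as from [read_hits()].
#' @param query_lengths Named numeric vector: candidate gene -> length (bp);
#'   every candidate must have a known length, and every hit must reference a
#'   known candidate.
#' @param identity_min,coverage_min The strict bounds (defaults 70 and 0.8).
#' @return Sorted character vector of novel gene ids.
#' @export
novel_genes <- function(hits, query_lengths, identity_min = 70, coverage_min = 0.8) {
  unknown <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(unknown) > 0) {
    flv_stop("hit table references unknown query gene: %s", unknown[1])
  }
  if (any(query_lengths <= 0)) flv_stop("query_length must be > 0")
  good <- hits$percent_identity > identity_min &
    (hits$alignment_length / query_lengths[hits$query_id]) > coverage_min
  known <- unique(hits$query_id[good])
  sort(setdiff(names(query_lengths), known))
}

#' Presence status of non-reference regions from coverage breadth
#'
#' @param fractions Named numeric vector region -> covered fraction.
#' @param present_threshold Present iff fraction >= this value (default 0.95).
#' @param missing_threshold Absent iff fraction < this value (default 0.5);
#'   everything between is truncated.
#' @return Named character vector of statuses in
#'   `{"present", "truncated", "absent"}`.
#' @export
nonreference_presence <- function(fractions, present_threshold = 0.95,
                                  missing_threshold = 0.5) {
  if (present_threshold < missing_threshold) {
    flv_stop("present_threshold must be >= missing_threshold")
  }
  status <- ifelse(fractions >= present_threshold, "present",
                   ifelse(fractions < missing_threshold, "absent", "truncated"))
  stats::setNames(status, names(fractions))
}
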