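# Gene-level aggregation of effect records, the polymorphism tiers, and a
# generic hypergeometric enrichment test with Holm–Bonferroni correction.

#' Per-gene variant summaries
#'
#' Aggregates primary effect records by gene. `n_total_sites` is the four-term
#' sum upstream + downstream + synonymous + missense used to rank polymorphic
#' genes; `n_deleterious` counts frameshift and stop/splice records;
#' `gene_dnds` is the per-gene missense/synonymous count ratio (`Inf` when
#' synonymous is 0 with missense > 0, `NaN` when both are 0).
#'
#' @param effects Data frame of primary effect records (one row per variant)
#'   with columns `gene_id` and `category`; intergenic records (`gene_id`
#'   `NA`) are ignored.
#' @return Data frame, one row per gene carrying >= 1 record, sorted by
#'   `gene_id`.
#' @export
per_gene_summary <- function(effects) {
  eff <- effects[!is.na(effects$gene_id), , drop = FALSE]
  ids <- sort(unique(eff$gene_id))
  cnt <- function(gid, what) sum(eff$gene_id == gid & eff$category %in% what)
  out <- data.frame(
    gene_id = ids,
    n_missense = vapply(ids, cnt, numeric(1), what = "missense"),
    n_synonymous = vapply(ids, cnt, numeric(1), what = "synonymous"),
    n_upstream = vapply(ids, cnt, numeric(1), what = "upstream"),
    n_downstream = vapply(ids, cnt, numeric(1), what = "downstream"),
    n_deleterious = vapply(ids, cnt, numeric(1), what = c("frameshift", "stop_splice")),
    stringsAsFactors = FALSE
  )
  out$n_total_sites <- out$n_upstream + out$n_downstream + out$n_synonymous + out$n_missense
  out$gene_dnds <- out$n_missense / out$n_synonymous
  rownames(out) <- NULL
  out
}

#' Highly polymorphic genes: >= `min_missense` missense variants
#' @param summaries As from [per_gene_summary()].
#' @param min_missense Inclusive threshold (default 2).
#' @return Sorted character vector of gene ids.
#' @export
select_highly_polymorphic <- function(summaries, min_missense = 2) {
  sort(summaries$gene_id[summaries$n_missense >= min_missense])
}

#' Promoter-mutated genes: >= `min_upstream` variants in the upstream window
#' @param summaries As from [per_gene_summary()].
#' @param min_upstream Inclusive threshold.
#' @return Sorted character vector of gene ids.
#' @export
select_promoter_mutated <- function(summaries, min_upstream = 2) {
  sort(summaries$gene_id[summaries$n_upstream >= min_upstream])
}

#' Extremely polymorphic genes: >= `min_total` sites and per-gene dN/dS > 1
#'
#' A gene with missense variants but zero synonymous variants (ratio `Inf`)
#' counts as exceeding 1; `NaN` (no coding variants) does not.
#'
#' @param summaries As from [per_gene_summary()].
#' @param min_total Inclusive threshold on `n_total_sites` (default 5).
#' @return Sorted character vector of gene ids.
#' @export
select_extremely_polymorphic <- function(summaries, min_total = 5) {
  pass_dnds <- !is.nan(summaries$gene_dnds) & summaries$gene_dnds > 1
  sort(summaries$gene_id[summaries$n_total_sites >= min_total & pass_dnds])
}

#' Genes with deleterious mutations
#'
#' Genes owning at least one frameshift or stop/splice (stop gained, stop
#' lost, splice region) record.
#'
#' @param effects Data frame of primary effect records.
#' @return Sorted character vector of gene ids.
#' @export
select_deleterious <- function(effects) {
  hit <- effects$category %in% c("frameshift", "stop_splice") & !is.na(effects$gene_id)
  sort(unique(effects$gene_id[hit]))
}

#' Hypergeometric term enrichment with Holm–Bonferroni correction
#'
#' For each term, tests over-representation of the selected gene set among the
#' term's genes with the hypergeometric upper tail (probability of observing
#' at least the seen overlap), then adjusts across terms by Holm–Bonferroni.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `background`).
#' @param term_map Data frame with columns `gene_id`, `term` (or a named list
#'   gene -> character vector of terms); genes outside the background are
#'   ignored.
#' @param background Character vector: the gene universe.
#' @param alpha Family-wise significance level for the `significant` flag
#'   (default 0.05).
#' @return Data frame per term: `term`, `k` (selected in term), `K` (term
#'   size), `n` (selected size), `N` (background size), `p`, `p_adj`,
#'   `significant`.
#' @export
enrichment <- function(selected, term_map, background, alpha = 0.05) {
  background <- unique(background)
  selected <- unique(selected)
  extra <- setdiff(selected, background)
  if (length(extra) > 0) {
    flv_stop("selected genes outside the background: %s",
             paste(utils::head(extra, 3), collapse = ", "))
  }
  if (is.list(term_map) && !is.data.frame(term_map)) {
    term_map <- data.frame(
      gene_id = rep(names(term_map), lengths(term_map)),
      term = unlist(term_map, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  by_term <- lapply(split(term_map$gene_id, term_map$term), unique)
  N <- length(background)
  n <- length(selected)
  res <- do.call(rbind, lapply(names(by_term), function(tm) {
    in_term <- by_term[[tm]]
    K <- length(in_term)
    k <- sum(in_term %in% selected)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    res <- data.frame(term = character(0), k = numeric(0), K = numeric(0),
                      n = numeric(0), N = numeric(0), p = numeric(0))
  }
  res$p_adj <- stats::p.adjust(res$p, method = "holm")
  res$significant <- res$p_adj < alpha
  res
}

#' Exact overlap between two gene sets
#' @param a,b Character vectors.
#' @return List with `n_overlap` and the sorted `overlap` vector.
#' @export
set_overlap <- function(a, b) {
  ov <- sort(intersect(unique(a), unique(b)))
  list(n_overlap = length(ov), overlap = ov)
}
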