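#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a universe of `N` genes of which `K` belong to the set, the chance
#' of an overlap at least as large as the one observed. Computed through
#' [stats::phyper()], which works on log scale internally, so small tails
#' are stable.
#'
#' @param k Observed overlap count.
#' @param n Query size (after universe restriction).
#' @param K Set size within the universe.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stopf("inconsistent counts: k=%d, n=%d, K=%d, N=%d (need 0 <= k <= min(n,K), n,K <= N)",
          k, n, K, N)
  }
  if (k == 0) return(1)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} m p_(j) / j`, clamped to at
#' most 1 and returned in the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return BH q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overlap-based gene-set enrichment
#'
#' Hypergeometric overlap enrichment of a query gene list against a
#' collection of gene sets, with BH correction across all tested sets — the
#' computation behind direction-split "FDR q-value" tables. The query is
#' first deduplicated (a gene contributes at most once to any overlap) and
#' restricted to the universe (dropped ids are reported via an attribute);
#' each set is likewise restricted, and sets with no members in the
#' universe are skipped.
#'
#' @param query Character vector of gene ids (e.g. one direction's direct
#'   targets mapped to genes).
#' @param sets Gene sets as returned by [read_gmt()].
#' @param universe Character vector of gene ids defining the background
#'   (e.g. all annotated autosomal genes).
#' @return Data frame of class `enrichment_result`, sorted by `q_value`
#'   then `p_value`: `set_name`, `k` (overlap), `n` (query size in
#'   universe), `K` (set size in universe), `N` (universe size), `p_value`,
#'   `q_value`. Attribute `n_dropped` counts query ids outside the universe.
#' @export
enrich_gene_sets <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("universe must be non-empty")
  query <- unique(query)
  n_dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(unique(s$members), universe)
    K <- length(members)
    if (!K) return(NULL)                     # skipped: no members in universe
    k <- length(intersect(query, members))
    data.frame(set_name = s$name, k = k, n = n, K = K, N = N,
               p_value = hypergeom_upper_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(set_name = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  }
  out$q_value <- if (nrow(out)) bh_adjust(out$p_value) else numeric(0)
  out <- out[order(out$q_value, out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Map transcript ids to gene ids
#'
#' Collapses transcript-level calls to genes before enrichment counting, so
#' a gene with several targeted transcripts contributes at most once.
#'
#' @param transcript_ids Character vector of transcript ids.
#' @param annotation A [transcript_annotation()].
#' @return Unique gene ids (unknown transcripts dropped with a warning).
#' @export
transcripts_to_genes <- function(transcript_ids, annotation) {
  idx <- match(transcript_ids, annotation$transcript_id)
  if (anyNA(idx)) {
    warnf("%d transcript id(s) not in the annotation were dropped",
          sum(is.na(idx)))
  }
  unique(annotation$gene_id[idx[!is.na(idx)]])
}
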