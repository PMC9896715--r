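#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` belong to the set.  The observed overlap
#' is included in the tail (standard over-representation convention).
#'
#' @param k Observed overlap.
#' @param K Set size within the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, k <= min(K, n), K <= N, n <= N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric test of a query gene list against each set of a GMT
#' collection, restricted to a background universe, with Benjamini-Hochberg
#' FDR across sets.  Query genes outside the background are dropped (count
#' reported via attribute).
#'
#' @param query_genes Character vector of query gene identifiers.
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param background_genes Background universe (e.g. all genes passing the
#'   expression filter).
#' @param fdr_alpha Enrichment FDR threshold (default 0.05).
#' @return `data.frame` ranked by FDR with set_name, overlap, set_size,
#'   query_size, background_size, p, fdr, enriched, overlap_genes
#'   (comma-separated); dropped-query count in `attr(, "n_dropped")`.
#' @export
enrich <- function(query_genes, gene_sets, background_genes,
                   fdr_alpha = 0.05) {
  background_genes <- unique(background_genes)
  query0 <- unique(query_genes)
  query <- intersect(query0, background_genes)
  n_dropped <- length(query0) - length(query)
  if (length(query) == 0)
    stop("empty query after intersection with the background")
  N <- length(background_genes)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    members <- intersect(gene_sets[[s]], background_genes)
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- if (K == 0) 1 else hypergeom_upper_tail(k, K, n, N)
    data.frame(set_name = s, overlap = k, set_size = K, query_size = n,
               background_size = N, p = p,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$enriched <- out$fdr < fdr_alpha
  out <- out[order(out$fdr, out$p, out$set_name),
             c("set_name", "overlap", "set_size", "query_size",
               "background_size", "p", "fdr", "enriched", "overlap_genes")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
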