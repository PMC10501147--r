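#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' (the DEG list) from a universe of `N` of which `K` belong to the
#' term, the probability of observing at least `k` term members.
#' Evaluated in log space via the regularized distribution function, so
#' extreme tails keep full accuracy.
#'
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @param n DEG-list size within the universe.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return Probability in `[0, 1]`. Vectorized over all arguments.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0 | k > n | n > N | K > N | k > K))
    stop("domain error: need 0 <= k <= min(n, K), n <= N, K <= N")
  # white balls = K (in term), drawn = n; P(X >= k) = P(X > k - 1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis of a DEG list
#'
#' Tests every annotation term for over-representation of the DEG list
#' in a fixed gene universe, adjusts across tested terms by
#' Benjamini-Hochberg, filters at both the raw and adjusted thresholds,
#' and ranks the survivors by overlap count, then gene ratio, then term
#' id. The q-value threshold used by common enrichment tools is
#' approximated here by the BH-adjusted p (monotone in the same
#' statistic; no external dependency).
#'
#' @param deg_genes Character vector of DEG symbols.
#' @param annotation Named list of character vectors (term -> genes), or
#'   a list of [signature_set()] objects.
#' @param universe Gene universe. Default: the union of all annotated
#'   genes; supply the platform's annotated genes to restrict the
#'   universe to what was measured.
#' @param p_max,adj_p_max Significance thresholds (both default 0.05).
#' @param top_m Number of top terms to return (default 10; `Inf` for
#'   all).
#' @return An object of class `enrich_result`: data frame with columns
#'   `term`, `k` (DEGs in term), `n` (DEGs in universe), `K` (universe
#'   genes in term), `N`, `gene_ratio`, `p`, `adj_p`, `genes`
#'   (comma-separated overlap).
#' @export
enrich_ora <- function(deg_genes, annotation, universe = NULL,
                       p_max = 0.05, adj_p_max = 0.05, top_m = 10) {
  if (!length(annotation)) stop("empty annotation")
  if (all(vapply(annotation, inherits, TRUE, "signature_set"))) {
    annotation <- stats::setNames(lapply(annotation, `[[`, "genes"),
                                  vapply(annotation, `[[`, "", "name"))
  }
  annotation <- lapply(annotation, function(g) unique(toupper(g)))
  if (is.null(names(annotation)) || any(!nzchar(names(annotation))))
    stop("annotation terms must be named")
  if (is.null(universe)) universe <- unique(unlist(annotation))
  universe <- unique(toupper(universe))
  N <- length(universe)
  degs <- intersect(unique(toupper(deg_genes)), universe)
  n <- length(degs)

  terms <- lapply(annotation, intersect, universe)
  K <- lengths(terms)
  tested <- K >= 1L
  terms <- terms[tested]
  K <- K[tested]
  if (!length(terms)) stop("no annotation term overlaps the universe")
  hits <- lapply(terms, intersect, degs)
  k <- lengths(hits)
  p <- hypergeom_upper_tail(k, n, K, N)
  adj <- bh_adjust(p)
  out <- data.frame(term = names(terms), k = k, n = n, K = K, N = N,
                    gene_ratio = if (n) k / n else NA_real_,
                    p = p, adj_p = adj,
                    genes = vapply(hits, function(g)
                      paste(sort(g), collapse = ","), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$p < p_max & out$adj_p < adj_p_max, , drop = FALSE]
  out <- out[order(-out$k, -out$gene_ratio, out$term), , drop = FALSE]
  out <- utils::head(out, top_m)
  rownames(out) <- NULL
  class(out) <- c("enrich_result", "data.frame")
  out
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf("Over-representation result: %d enriched term(s)\n", nrow(x)))
  if (nrow(x))
    print(as.data.frame(x[, c("term", "k", "n", "K", "N", "gene_ratio",
                              "p", "adj_p")]), row.names = FALSE)
  invisible(x)
}
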