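#' Upper-tail hypergeometric test
#'
#' Probability of observing at least `k` annotated genes in a query of
#' size `n` drawn from a universe of `M` genes of which `K` are
#' annotated: `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`.
#'
#' @param k Observed hits in the query.
#' @param K Annotated genes in the universe (set size after
#'   intersection with the universe).
#' @param n Query size.
#' @param M Universe size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_test(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_test <- function(k, K, n, M) {
  for (v in list(k = k, K = K, n = n, M = M)) {
    if (!is_count(v, min = 0L)) abort("counts must be non-negative integers")
  }
  if (K > M || n > M) abort("set size and query size cannot exceed the universe")
  if (k > min(K, n)) abort("hits k cannot exceed min(K, n)")
  if (k < max(0L, n + K - M)) abort("hits k below the feasible minimum")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list against a collection
#'
#' Hypergeometric over-representation analysis on a discrete gene list:
#' each set is intersected with the universe, sets left with at least
#' one member are tested for enrichment of the query, and p-values are
#' Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param query Character vector of query genes (e.g. an up-regulated
#'   list); must be a subset of `universe`.
#' @param universe Character vector of background genes (typically all
#'   genes tested for differential expression).
#' @param collection A [gene_set_collection()].
#' @return A `data.frame` sorted by p with columns `set_name`, `k`
#'   (hits), `K` (set size in universe), `n` (query size), `M`
#'   (universe size), `p` and `q`.
#' @export
run_ora <- function(query, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort("query gene '", outside[1L], "' is not in the universe")
  }
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(s) {
    members <- intersect(collection$sets[[s]], universe)
    if (!length(members)) {
      return(NULL)
    }
    k <- length(intersect(query, members))
    data.frame(
      set_name = s, k = k, K = length(members), n = n, M = M,
      p = hypergeom_test(k, length(members), n, M),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) abort("no set overlaps the universe")
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set_name), , drop = FALSE]
}
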