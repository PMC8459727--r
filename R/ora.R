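#' One-sided Fisher's exact test (hypergeometric upper tail)
#'
#' Probability of observing an overlap at least as large as `k` between a
#' query of size `n` and a gene set of size `K` drawn from a universe of
#' size `N`:
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}}
#' Computed via the exact hypergeometric survival function. All arguments
#' are vectorized.
#'
#' @param k overlap count, `0 <= k <= min(n, K)`.
#' @param n query size within the universe.
#' @param K gene-set size within the universe.
#' @param N universe size.
#' @return exact one-sided p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' fisher_right_tail(3, 6, 5, 20)
fisher_right_tail <- function(k, n, K, N) {
  if (any(k != floor(k) | n != floor(n) | K != floor(K) | N != floor(N)))
    pc_stop("counts must be integers")
  if (any(K < 0 | K > N | n < 0 | n > N))
    pc_stop("need 0 <= K <= N and 0 <= n <= N")
  if (any(k < 0 | k > pmin(n, K)))
    pc_stop("need 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Yekutieli adjustment (FDR under dependency)
#'
#' Step-up adjustment valid under arbitrary dependence between tests: with
#' order statistics \eqn{p_{(1)} \le \dots \le p_{(m)}} and
#' \eqn{c(m) = \sum_{j=1}^m 1/j}, the raw adjusted value is
#' \eqn{p_{(i)} \, m \, c(m) / i}, then the running minimum from the top is
#' taken and capped at 1. Values are returned in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, length >= 1.
#' @return adjusted p-values in input order.
#' @export
adjust_by <- function(pvals) {
  if (length(pvals) == 0L) pc_stop("empty p-value vector")
  if (any(is.na(pvals) | pvals < 0 | pvals > 1))
    pc_stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BY")
}

#' Over-representation analysis over a gene-set collection
#'
#' One one-sided Fisher's exact test per gene set, testing whether the
#' query gene list over-represents the set relative to the universe,
#' followed by Benjamini-Yekutieli correction across the collection's
#' surviving tests (each database collection is treated as its own family
#' of tests).
#'
#' The universe defaults to the union of all genes in the collection; pass
#' the measured gene background to override. The query and each gene set
#' are intersected with the universe before testing. Gene sets falling
#' entirely outside the universe, or outside `[min_size, max_size]` after
#' intersection, are excluded (with a warning / recorded in metadata).
#' `alpha` only sets the `significant` flag; it never alters p-values.
#'
#' @param query_genes character vector of HGNC symbols of interest.
#' @param collection a [gene_set_collection()].
#' @param universe background gene symbols; `NULL` for the collection
#'   union.
#' @param alpha significance level for the `significant` flag.
#' @param min_size,max_size gene-set size filter (applied to the in-universe
#'   set size `K`).
#' @return data.frame with columns `set_id`, `database`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `significant`, ordered by `p_adj` then `p`;
#'   attribute `metadata` records universe definition, `alpha` and filters.
#' @export
run_ora <- function(query_genes, collection, universe = NULL, alpha = 0.05,
                    min_size = 3L, max_size = 1000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) pc_stop("empty gene-set collection")
  universe_mode <- if (is.null(universe)) "collection_union" else
    "user_supplied"
  if (is.null(universe)) universe <- collection_universe(collection)
  universe <- unique(normalize_symbols(universe))
  query <- intersect(unique(normalize_symbols(query_genes)), universe)
  if (length(query) == 0L)
    pc_stop("no query gene is present in the universe; check that the ",
            "query uses HGNC symbols matching the gene-set databases")

  n <- length(query); N <- length(universe)
  rows <- lapply(collection$sets, function(s) {
    sg <- intersect(s$genes, universe)
    data.frame(set_id = s$set_id, K = length(sg),
               k = length(intersect(query, sg)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  outside <- df$set_id[df$K == 0L]
  if (length(outside))
    pc_warn(length(outside), " gene set(s) entirely outside the universe ",
            "excluded: ", paste(utils::head(outside, 5L), collapse = ", "))
  filtered <- df$set_id[df$K > 0L & (df$K < min_size | df$K > max_size)]
  df <- df[df$K >= min_size & df$K <= max_size, , drop = FALSE]
  if (nrow(df) == 0L)
    pc_stop("no gene set survives the size filters [", min_size, ", ",
            max_size, "]")

  df$n <- n; df$N <- N
  df$database <- collection$database
  df$p <- fisher_right_tail(df$k, n, df$K, N)
  df$p_adj <- adjust_by(df$p)
  df$significant <- df$p_adj < alpha
  df <- df[order(df$p_adj, df$p, df$set_id),
           c("set_id", "database", "k", "K", "n", "N", "p", "p_adj",
             "significant")]
  rownames(df) <- NULL
  attr(df, "metadata") <- list(
    method = "ORA", universe = universe_mode, universe_size = N,
    query_size = n, alpha = alpha, min_size = min_size,
    max_size = max_size, correction = "BY",
    excluded_outside_universe = outside, excluded_size_filter = filtered)
  df
}
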