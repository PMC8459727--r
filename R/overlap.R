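#' Venn-region decomposition of equivalent gene sets
#'
#' Partitions the union of 2-4 gene sets into the exclusive and shared
#' regions of their Venn diagram. Each gene is assigned the membership
#' signature (one bit per set, in input order; `"101"` = in sets 1 and 3)
#' of the sets containing it; the non-empty signatures partition the union.
#'
#' @param gene_sets named list of 2-4 non-empty character vectors of gene
#'   symbols (names identify the sets, e.g. `"KEGG:hsa00620"`).
#' @return a `region_decomposition`: list with `sets` (the input names)
#'   and `regions`, a list named by signature holding sorted gene vectors,
#'   ordered by descending binary signature (all-shared region first).
#' @export
venn_decompose <- function(gene_sets) {
  k <- length(gene_sets)
  if (k < 2L || k > 4L)
    pc_stop("Venn decomposition supports 2 to 4 sets, got ", k,
            " (use pairwise overlap tables for larger families)")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets))))
    names(gene_sets) <- paste0("set", seq_len(k))
  gene_sets <- lapply(gene_sets, function(g) unique(normalize_symbols(g)))
  if (any(lengths(gene_sets) == 0L))
    pc_stop("empty gene set in Venn decomposition")
  all_genes <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  member <- vapply(gene_sets, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = k)
  sig <- apply(member, 1L, function(b) paste(as.integer(b), collapse = ""))
  regions <- split(all_genes, sig)
  regions <- lapply(regions, sort)
  ## descending binary order: full-overlap signature first
  regions <- regions[order(strtoi(names(regions), base = 2L),
                           decreasing = TRUE)]
  structure(list(sets = names(gene_sets), regions = regions),
            class = "region_decomposition")
}

#' @export
print.region_decomposition <- function(x, ...) {
  cat(sprintf("region_decomposition of %d sets (%s): %d non-empty regions\n",
              length(x$sets), paste(x$sets, collapse = ", "),
              length(x$regions)))
  for (s in names(x$regions))
    cat(sprintf("  %s: %d genes\n", s, length(x$regions[[s]])))
  invisible(x)
}

#' Annotate Venn regions with fold changes
#'
#' Attaches, per region, the histogram and mean of log2 fold changes of the
#' region's genes found in a differential-expression table. All regions
#' share one set of bin edges, so summaries are additive: the union's bin
#' counts equal the elementwise sum over regions. Region genes absent from
#' the DGE table are counted separately (`missing`), never silently
#' dropped.
#'
#' Default bins: 21 equal-width bins spanning the observed log2fc range of
#' the union's genes, symmetrized about 0; the edges used are recorded in
#' the result.
#'
#' @param decomp a [venn_decompose()] result.
#' @param dge a [dge_table()].
#' @param bins numeric vector of strictly increasing bin edges, or `NULL`
#'   for the default.
#' @param p_adj_max optional filter: only DGE rows with `p_adj` below this
#'   value are used (default `NULL`, all rows).
#' @return the decomposition with added `bins` (edges) and `summaries`, a
#'   per-region list of `n`, `n_in_dge`, `missing`, `mean_log2fc`,
#'   `counts`.
#' @export
annotate_fold_changes <- function(decomp, dge, bins = NULL,
                                  p_adj_max = NULL) {
  stopifnot(inherits(decomp, "region_decomposition"),
            inherits(dge, "dge_table"))
  if (!is.null(p_adj_max)) dge <- dge[dge$p_adj < p_adj_max, , drop = FALSE]
  fc <- stats::setNames(dge$log2fc, dge$gene)
  union_genes <- unlist(decomp$regions, use.names = FALSE)
  have <- intersect(union_genes, names(fc))
  if (!length(have))
    pc_warn("no region gene found in the DGE table; summaries are empty")
  if (is.null(bins)) {
    r <- if (length(have)) max(abs(fc[have])) else 1
    if (r == 0) r <- 1
    bins <- seq(-r, r, length.out = 22L)
  }
  if (any(diff(bins) <= 0)) pc_stop("bin edges must be strictly increasing")

  decomp$bins <- bins
  decomp$summaries <- lapply(decomp$regions, function(genes) {
    v <- fc[intersect(genes, names(fc))]
    counts <- if (length(v))
      graphics::hist(pmin(pmax(v, bins[1L]), bins[length(bins)]),
                     breaks = bins, plot = FALSE)$counts
    else integer(length(bins) - 1L)
    list(n = length(genes), n_in_dge = length(v),
         missing = length(genes) - length(v),
         mean_log2fc = if (length(v)) mean(v) else NA_real_,
         counts = counts)
  })
  decomp
}

#' Gene-level explanation of a cross-database discrepancy
#'
#' For an equivalence group whose member databases disagree, decomposes the
#' member gene sets into Venn regions, annotates them with fold changes,
#' and orders the exclusive regions (genes unique to one database's
#' representation) by the magnitude of their mean log2 fold change —
#' surfacing the genes most likely to drive the contradiction, e.g. a
#' block of genes unique to one database's gene set that carries a
#' directional signal the shared core lacks.
#'
#' @param group an `equivalence_group` with 2-4 members (larger families
#'   fall back to a pairwise overlap table).
#' @param results_by_db optional named list of per-database statistics
#'   (as in [classify_group()]), echoed into the report.
#' @param dge optional [dge_table()]; without it the report is limited to
#'   set-membership counts.
#' @param bins histogram bin edges, see [annotate_fold_changes()].
#' @return a `discrepancy_report`: list with `group_id`, `sets`,
#'   `full_overlap` flag, `regions` (data.frame: signature, exclusive_to,
#'   n, n_in_dge, mean_log2fc — exclusive regions first, ordered by
#'   |mean log2fc| descending), `decomposition` (annotated, when k <= 4),
#'   `pairwise` (fallback table, when k > 4) and `stats` (the echoed
#'   per-database statistics).
#' @export
explain_discrepancy <- function(group, results_by_db = NULL, dge = NULL,
                                bins = NULL) {
  stopifnot(inherits(group, "equivalence_group"))
  if (length(group$member_genes) < 2L)
    pc_stop("group ", group$group_id, " has fewer than 2 members; nothing ",
            "to compare")
  sets <- group$member_genes
  names(sets) <- pc_key(group$members$database, group$members$set_id)

  if (length(sets) > 4L) {
    pairs <- utils::combn(names(sets), 2L)
    pw <- data.frame(
      set_a = pairs[1L, ], set_b = pairs[2L, ],
      n_a = lengths(sets)[pairs[1L, ]], n_b = lengths(sets)[pairs[2L, ]],
      shared = apply(pairs, 2L, function(p)
        length(intersect(sets[[p[1L]]], sets[[p[2L]]]))),
      stringsAsFactors = FALSE)
    pw$jaccard <- pw$shared / (pw$n_a + pw$n_b - pw$shared)
    return(structure(list(group_id = group$group_id, sets = names(sets),
                          full_overlap = all(pw$jaccard == 1),
                          regions = NULL, decomposition = NULL,
                          pairwise = pw, stats = results_by_db),
                     class = "discrepancy_report"))
  }

  decomp <- venn_decompose(sets)
  if (!is.null(dge)) decomp <- annotate_fold_changes(decomp, dge, bins)

  sigs <- names(decomp$regions)
  exclusive_to <- vapply(sigs, function(s) {
    bits <- strsplit(s, "")[[1L]] == "1"
    if (sum(bits) == 1L) decomp$sets[bits] else NA_character_
  }, character(1))
  regions <- data.frame(
    signature = sigs,
    exclusive_to = exclusive_to,
    n = lengths(decomp$regions),
    n_in_dge = if (!is.null(dge))
      vapply(decomp$summaries, `[[`, integer(1), "n_in_dge") else
      NA_integer_,
    mean_log2fc = if (!is.null(dge))
      vapply(decomp$summaries, `[[`, numeric(1), "mean_log2fc") else
      NA_real_,
    stringsAsFactors = FALSE)
  ## exclusive regions first, strongest directional signal on top
  ord <- order(is.na(regions$exclusive_to),
               -abs(ifelse(is.na(regions$mean_log2fc), -Inf,
                           regions$mean_log2fc)))
  regions <- regions[ord, ]
  rownames(regions) <- NULL

  structure(list(group_id = group$group_id, sets = decomp$sets,
                 full_overlap = length(decomp$regions) == 1L &&
                   !any(grepl("0", names(decomp$regions))),
                 regions = regions, decomposition = decomp,
                 pairwise = NULL, stats = results_by_db),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("discrepancy_report for %s (%d sets)\n", x$group_id,
              length(x$sets)))
  if (x$full_overlap) cat("  member gene sets overlap fully\n")
  if (!is.null(x$regions)) print(x$regions)
  invisible(x)
}

#' Serialize a region decomposition as JSON
#'
#' @param decomp an annotated or plain [venn_decompose()] result.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
region_json <- function(decomp, path = NULL) {
  regions <- lapply(names(decomp$regions), function(s) {
    out <- list(signature = s, genes = decomp$regions[[s]],
                n = length(decomp$regions[[s]]))
    if (!is.null(decomp$summaries)) {
      sm <- decomp$summaries[[s]]
      out$mean_log2fc <- sm$mean_log2fc
      out$counts <- sm$counts
      out$missing <- sm$missing
    }
    out
  })
  obj <- list(sets = decomp$sets, regions = regions)
  if (!is.null(decomp$bins)) obj$bins <- decomp$bins
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
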