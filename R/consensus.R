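CONSENSUS_LABELS <- c("concordant_significant", "concordant_nonsignificant",
                      "contradictory_significance", "contradictory_direction",
                      "single_database")

#' Classify the cross-database consensus of one equivalence group
#'
#' Given the per-database enrichment results for one group of equivalent
#' pathways, assigns exactly one label:
#' \describe{
#'   \item{`single_database`}{the pathway has a result in only one
#'     database — no comparison is possible.}
#'   \item{`concordant_significant`}{significant (adjusted statistic below
#'     `alpha`) in every database where it exists, and, for score-based
#'     methods, with agreeing NES signs.}
#'   \item{`concordant_nonsignificant`}{non-significant everywhere. Kept as
#'     a distinct label (not folded into "concordant") so either counting
#'     convention can be recomputed from the output.}
#'   \item{`contradictory_significance`}{significant in one or more
#'     databases but not in the others.}
#'   \item{`contradictory_direction`}{score-based methods only: at least
#'     two significant members disagree in the sign of the NES (the same
#'     pathway enriched at the top of the ranking for one database and at
#'     the bottom for another). Direction conflict takes precedence over
#'     significance concordance.}
#' }
#' Only databases in which the pathway exists and has a result are
#' compared: absence is never treated as non-significance.
#'
#' @param group an `equivalence_group`.
#' @param results_by_db named list (database -> list with `p_adj` and,
#'   for score-based methods, `nes`) for this group's members.
#' @param alpha significance level applied to the adjusted statistic.
#' @param method_kind `"ORA_like"` (significance only) or `"score_based"`
#'   (significance + NES direction).
#' @return a `consensus_record`: list with `group_id`, `group_name`,
#'   `per_database` (data.frame: database, present, p_adj, nes, significant,
#'   direction) and `label`.
#' @export
classify_group <- function(group, results_by_db, alpha = 0.05,
                           method_kind = c("score_based", "ORA_like")) {
  method_kind <- match.arg(method_kind)
  dbs <- names(results_by_db)
  if (length(dbs) == 0L)
    pc_stop("group ", group$group_id, " has no results in any database")
  padj <- vapply(results_by_db, function(r) as.numeric(r$p_adj), numeric(1))
  nes <- vapply(results_by_db, function(r)
    if (!is.null(r$nes)) as.numeric(r$nes) else NA_real_, numeric(1))
  sig <- padj < alpha
  direction <- rep("n/a", length(dbs))
  if (method_kind == "score_based")
    direction <- ifelse(is.na(nes), "n/a", ifelse(nes >= 0, "+", "-"))

  label <- if (length(dbs) == 1L) {
    "single_database"
  } else if (all(sig)) {
    sg <- sign(nes[sig])
    if (method_kind == "score_based" && length(unique(sg[!is.na(sg)])) > 1L)
      "contradictory_direction" else "concordant_significant"
  } else if (!any(sig)) {
    "concordant_nonsignificant"
  } else {
    "contradictory_significance"
  }

  structure(list(
    group_id = group$group_id,
    group_name = group$group_name,
    per_database = data.frame(database = dbs, present = TRUE,
                              p_adj = unname(padj), nes = unname(nes),
                              significant = unname(sig),
                              direction = direction,
                              stringsAsFactors = FALSE),
    label = label, method_kind = method_kind, alpha = alpha),
    class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("consensus_record %s ('%s'): %s [%d database(s)]\n",
              x$group_id, x$group_name, x$label, nrow(x$per_database)))
  invisible(x)
}

#' Cross-database consensus table
#'
#' Aligns enrichment result rows to equivalence groups via
#' `(database, set_id)` and classifies every group that has at least one
#' result. Rows whose `(database, set_id)` matches no known pathway are
#' collected in the `unresolved` element (never dropped silently). Rows
#' from the merged meta-database (`meta_label`) are displayed alongside in
#' a dedicated column block but excluded from the consensus label.
#'
#' @param groups equivalence groups ([build_equivalence_groups()]).
#' @param results data.frame of enrichment rows with columns `set_id`,
#'   `database`, an adjusted statistic (`p_adj` or `q_fdr`; auto-detected)
#'   and optionally `nes`. Outputs of [run_ora()], [run_gsea()],
#'   [run_prerank()] (possibly `rbind`-ed across databases) qualify, as do
#'   imported tables ([import_results()]).
#' @param alpha significance level.
#' @param method_kind see [classify_group()]; default guessed from the
#'   presence of an `nes` column.
#' @param meta_label database label of the merged meta-collection.
#' @return list with `records` (wide data.frame: group_id, name,
#'   n_databases, label, then `<db>.present` / `<db>.p_adj` / `<db>.nes`
#'   column blocks), `summary` (named counts per label), `unresolved`
#'   (data.frame of unmatched rows) and `record_list` (the
#'   `consensus_record` objects).
#' @export
consensus_table <- function(groups, results, alpha = 0.05,
                            method_kind = NULL, meta_label = "META") {
  stat_col <- intersect(c("p_adj", "q_fdr"), names(results))
  if (!length(stat_col))
    pc_stop("results need an adjusted statistic column ('p_adj' or 'q_fdr')")
  stat_col <- stat_col[1L]
  has_nes <- "nes" %in% names(results)
  if (is.null(method_kind))
    method_kind <- if (has_nes) "score_based" else "ORA_like"

  idx <- group_index(groups)
  meta_ids <- names(groups)
  is_meta <- results$database == meta_label
  key <- pc_key(results$database, results$set_id)
  gid <- unname(idx[key])
  ## meta-collection rows resolve by group id directly
  gid[is_meta & results$set_id %in% meta_ids] <-
    results$set_id[is_meta & results$set_id %in% meta_ids]
  unresolved <- results[is.na(gid), , drop = FALSE]
  if (nrow(unresolved))
    pc_warn(nrow(unresolved), " result row(s) reference unknown pathways; ",
            "collected in the unresolved report")
  res <- results[!is.na(gid), , drop = FALSE]
  gid <- gid[!is.na(gid)]
  is_meta <- res$database == meta_label

  records <- list()
  for (g in groups) {
    rows <- which(gid == g$group_id & !is_meta)
    if (!length(rows)) next
    by_db <- lapply(rows, function(i) list(
      p_adj = res[[stat_col]][i],
      nes = if (has_nes) res$nes[i] else NULL))
    names(by_db) <- res$database[rows]
    if (anyDuplicated(names(by_db)))
      pc_stop("multiple result rows for group ", g$group_id,
              " in database ", names(by_db)[duplicated(names(by_db))][1L])
    records[[g$group_id]] <- classify_group(g, by_db, alpha, method_kind)
  }
  if (!length(records))
    return(list(records = data.frame(), summary = empty_summary(),
                unresolved = unresolved, record_list = list()))

  all_dbs <- sort(unique(unlist(lapply(records, function(r)
    r$per_database$database))))
  wide <- do.call(rbind, lapply(records, function(r) {
    row <- data.frame(group_id = r$group_id, name = r$group_name,
                      n_databases = nrow(r$per_database), label = r$label,
                      stringsAsFactors = FALSE)
    for (db in all_dbs) {
      i <- match(db, r$per_database$database)
      row[[paste0(db, ".present")]] <- !is.na(i)
      row[[paste0(db, ".p_adj")]] <- if (is.na(i)) NA_real_ else
        r$per_database$p_adj[i]
      row[[paste0(db, ".nes")]] <- if (is.na(i)) NA_real_ else
        r$per_database$nes[i]
    }
    row
  }))
  ## meta-database rows shown alongside, never counted in labels
  meta_rows <- which(is_meta)
  wide[[paste0(meta_label, ".p_adj")]] <- res[[stat_col]][meta_rows][
    match(wide$group_id, gid[meta_rows])]
  if (has_nes)
    wide[[paste0(meta_label, ".nes")]] <-
      res$nes[meta_rows][match(wide$group_id, gid[meta_rows])]
  rownames(wide) <- NULL

  summ <- empty_summary()
  tab <- table(wide$label)
  summ[names(tab)] <- as.integer(tab)
  list(records = wide, summary = summ, unresolved = unresolved,
       record_list = records)
}

empty_summary <- function() {
  stats::setNames(integer(length(CONSENSUS_LABELS)), CONSENSUS_LABELS)
}

#' Compare consensus labels between two methods
#'
#' Cross-tabulates two consensus analyses (e.g. ORA vs GSEA) over their
#' shared equivalence groups: how many groups are concordant
#' (`concordant_*` label) in both, in exactly one, or in neither, plus a
#' per-group side-by-side label table. Groups outside the intersection are
#' dropped with a warning.
#'
#' @param records_a,records_b outputs of [consensus_table()] (or their
#'   `records` data.frames).
#' @return list with `summary` (named counts: `common_concordant`,
#'   `only_a_concordant`, `only_b_concordant`, `neither`, `n_common`) and
#'   `table` (group_id, label_a, label_b).
#' @export
compare_methods <- function(records_a, records_b) {
  a <- if (is.list(records_a) && !is.data.frame(records_a))
    records_a$records else records_a
  b <- if (is.list(records_b) && !is.data.frame(records_b))
    records_b$records else records_b
  common <- intersect(a$group_id, b$group_id)
  if (!length(common))
    pc_warn("no equivalence group is shared between the two record sets")
  if (length(common) < max(nrow(a), nrow(b)))
    pc_warn("group universes differ; comparison restricted to the ",
            length(common), " shared group(s)")
  la <- a$label[match(common, a$group_id)]
  lb <- b$label[match(common, b$group_id)]
  ca <- startsWith(la, "concordant")
  cb <- startsWith(lb, "concordant")
  list(summary = c(common_concordant = sum(ca & cb),
                   only_a_concordant = sum(ca & !cb),
                   only_b_concordant = sum(!ca & cb),
                   neither = sum(!ca & !cb),
                   n_common = length(common)),
       table = data.frame(group_id = common, label_a = la, label_b = lb,
                          stringsAsFactors = FALSE))
}

#' Import an externally computed enrichment result table
#'
#' Accepts results of any enrichment method run outside this package
#' (upload contract: columns `set_id`, `database`, `p_adj` — or `p`, used
#' as-is if no adjusted value is supplied — and optionally `es`/`nes` for
#' score-based methods). Rows are attached to equivalence groups via
#' `(database, set_id)`; unmatched rows are reported, not dropped.
#' Duplicate `(database, set_id)` rows are an error. An example upload
#' file ships at
#' `system.file("extdata", "example_upload.tsv", package = "pathconsensus")`.
#'
#' @param table data.frame following the upload contract.
#' @param groups equivalence groups.
#' @param method label recorded on the output (e.g. `"EnrichNet"`).
#' @return data.frame of matched rows (columns `set_id`, `database`,
#'   `p_adj`, `nes`, `group_id`) ready for [consensus_table()], with
#'   attributes `unresolved` (unmatched rows) and `method`.
#' @export
import_results <- function(table, groups, method = "imported") {
  need <- c("set_id", "database")
  missing <- setdiff(need, names(table))
  if (length(missing))
    pc_stop("imported table is missing column(s): ",
            paste(missing, collapse = ", "))
  if (!"p_adj" %in% names(table)) {
    if (!"p" %in% names(table))
      pc_stop("imported table needs a 'p_adj' (or 'p') column")
    table$p_adj <- table$p
  }
  if (!"nes" %in% names(table)) table$nes <- NA_real_
  key <- pc_key(table$database, table$set_id)
  dup <- duplicated(key)
  if (any(dup))
    pc_stop("duplicate (database, set_id) row(s) in imported table: ",
            paste(utils::head(paste(table$database[dup],
                                    table$set_id[dup]), 3L),
                  collapse = "; "))
  idx <- group_index(groups)
  gid <- unname(idx[key])
  unresolved <- table[is.na(gid), , drop = FALSE]
  if (nrow(unresolved))
    pc_warn(nrow(unresolved), " imported row(s) match no known pathway")
  out <- table[!is.na(gid), c("set_id", "database", "p_adj", "nes"),
               drop = FALSE]
  out$group_id <- gid[!is.na(gid)]
  rownames(out) <- NULL
  attr(out, "unresolved") <- unresolved
  attr(out, "method") <- method
  out
}
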