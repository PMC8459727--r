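DEFAULT_CATEGORY_ROOTS <- c("metabolism", "immune", "signaling",
                            "communication and transport", "cell death",
                            "disease", "DNA repair and replication", "others")

#' Build the pathway hierarchy
#'
#' Assembles the directed acyclic graph of pathways and top-level
#' categories from `isPartOf` mapping records, after equivalent pathways
#' have been collapsed to single nodes by [build_equivalence_groups()].
#' Edges point child -> parent. `isPartOf` endpoints are resolved to the
#' merged group node when the referenced database pathway belongs to a
#' group, or to a declared category root when the identifier (or name)
#' matches one; unresolved endpoints are excluded and reported.
#'
#' Validation: a cycle is fatal (the error names one cycle); nodes with no
#' path to a root are reported as orphans (warning); depth is counted with
#' the root categories at depth 1 and a maximum root-to-leaf depth above
#' `max_depth` marks the hierarchy invalid (flag, not an error). The
#' published four-database hierarchy satisfies 8 roots and depth <= 4.
#'
#' @param mappings mapping records; only `isPartOf` rows are used.
#' @param groups equivalence groups ([build_equivalence_groups()]).
#' @param category_roots character vector of top-level category names.
#' @param max_depth maximum allowed root-to-leaf depth (inclusive).
#' @return a `pathway_hierarchy`: list with `graph` (igraph, child ->
#'   parent), `roots`, `nodes` (data.frame: node_id, name, kind, size,
#'   depth), `max_depth_observed`, `valid`, and `issues` (data.frame:
#'   issue, node, detail).
#' @export
build_hierarchy <- function(mappings, groups,
                            category_roots = DEFAULT_CATEGORY_ROOTS,
                            max_depth = 4L) {
  idx <- group_index(groups)
  gname <- stats::setNames(vapply(groups, `[[`, character(1), "group_name"),
                           vapply(groups, `[[`, character(1), "group_id"))
  gsize <- stats::setNames(vapply(groups, function(g) length(g$genes),
                                  integer(1)), names(gname))

  resolve <- function(db, id, nm) {
    k <- pc_key(db, id)
    if (k %in% names(idx)) return(unname(idx[k]))
    if (id %in% names(gname)) return(id)  # group ids usable directly
    if (id %in% category_roots) return(id)
    if (nm %in% category_roots) return(nm)
    NA_character_
  }

  po <- mappings[mappings$relation == "isPartOf", , drop = FALSE]
  issues <- data.frame(issue = character(0), node = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  from <- to <- character(nrow(po))
  for (i in seq_len(nrow(po))) {
    from[i] <- resolve(po$source_db[i], po$source_id[i], po$source_name[i])
    to[i]   <- resolve(po$target_db[i], po$target_id[i], po$target_name[i])
  }
  bad <- is.na(from) | is.na(to)
  if (any(bad)) {
    issues <- rbind(issues, data.frame(
      issue = "unresolved_is_part_of",
      node = ifelse(is.na(from[bad]), po$source_id[bad], po$target_id[bad]),
      detail = "isPartOf endpoint matches no known pathway or category",
      stringsAsFactors = FALSE))
    pc_warn(sum(bad), " isPartOf record(s) with unresolved endpoints excluded")
  }
  edges <- unique(data.frame(from = from[!bad], to = to[!bad],
                             stringsAsFactors = FALSE))
  edges <- edges[edges$from != edges$to, , drop = FALSE]

  node_ids <- unique(c(category_roots, names(gname), edges$from, edges$to))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))

  if (!igraph::is_dag(g)) {
    sccs <- igraph::components(g, mode = "strong")
    cyc <- names(sccs$membership)[sccs$membership ==
                                    which(sccs$csize > 1L)[1L]]
    pc_stop("pathway hierarchy contains a cycle: ",
            paste(cyc, collapse = " -> "), " -> ", cyc[1L])
  }

  ## orphans: non-root nodes that cannot reach any declared root
  reach <- unique(unlist(lapply(
    intersect(category_roots, node_ids),
    function(r) names(igraph::subcomponent(g, r, mode = "in")))))
  orphans <- setdiff(node_ids, reach)
  if (length(orphans)) {
    issues <- rbind(issues, data.frame(
      issue = "orphan", node = orphans,
      detail = "no isPartOf path to a declared category root",
      stringsAsFactors = FALSE))
    pc_warn(length(orphans), " node(s) have no path to a category root")
  }

  ## depth = longest path from a root, roots at depth 1; computed in
  ## reverse topological order over child -> parent edges
  depth <- stats::setNames(rep(NA_real_, length(node_ids)), node_ids)
  depth[intersect(category_roots, node_ids)] <- 1
  topo <- names(igraph::topo_sort(g, mode = "in"))  # parents before children
  for (v in topo) {
    parents <- names(igraph::neighbors(g, v, mode = "out"))
    if (length(parents) && any(!is.na(depth[parents])))
      depth[v] <- max(depth[parents], na.rm = TRUE) + 1
  }
  max_obs <- if (all(is.na(depth))) 0L else as.integer(max(depth, na.rm = TRUE))
  valid <- TRUE
  if (max_obs > max_depth) {
    valid <- FALSE
    deep <- names(depth)[!is.na(depth) & depth > max_depth]
    issues <- rbind(issues, data.frame(
      issue = "depth_exceeded", node = deep,
      detail = sprintf("depth %d > maximum %d", as.integer(depth[deep]),
                       max_depth),
      stringsAsFactors = FALSE))
  }

  nodes <- data.frame(
    node_id = node_ids,
    name = ifelse(node_ids %in% names(gname), gname[node_ids], node_ids),
    kind = ifelse(node_ids %in% category_roots, "category", "pathway"),
    size = ifelse(node_ids %in% names(gsize), gsize[node_ids], 0L),
    depth = depth[node_ids],
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  structure(list(graph = g, roots = intersect(category_roots, node_ids),
                 nodes = nodes, max_depth_observed = max_obs,
                 max_depth_allowed = as.integer(max_depth),
                 valid = valid, issues = issues),
            class = "pathway_hierarchy")
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat(sprintf(paste0("pathway_hierarchy: %d nodes (%d categories), ",
                     "%d edges, max depth %d, %s\n"),
              nrow(x$nodes), length(x$roots), igraph::ecount(x$graph),
              x$max_depth_observed,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Validation report for a hierarchy
#'
#' @param hierarchy a `pathway_hierarchy`.
#' @param path optional TSV output path (columns issue, node, detail).
#' @return the issues data.frame, invisibly if written to `path`.
#' @export
hierarchy_validation_report <- function(hierarchy, path = NULL) {
  issues <- hierarchy$issues
  if (!is.null(path)) {
    utils::write.table(issues, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(issues))
  }
  issues
}

#' Export the hierarchy as a circle-pack tree
#'
#' Converts the hierarchy DAG into the nested-tree structure used for
#' circle-packing layouts, attaching enrichment results as node color
#' semantics. Because a circle packing is a strict nesting, a node with k
#' parents is duplicated under each parent.
#'
#' Color semantics follow the method: for score-based (GSEA-like) results,
#' nodes whose adjusted statistic is not below `alpha` are flagged
#' non-significant (rendered gray) and significant nodes carry the signed
#' NES as `color_value` (red/blue by sign, shaded by magnitude); for ORA,
#' `significant` is `TRUE` iff the adjusted p-value is below `alpha` and no
#' NES color value exists. Node `size` is the gene-set cardinality.
#'
#' Results for pathways absent from the hierarchy are attached, with a
#' warning, under a catch-all `"unmapped"` root.
#'
#' @param hierarchy a `pathway_hierarchy`.
#' @param results data.frame with column `node_id` (group ids), an adjusted
#'   statistic column (`p_adj` or `q_fdr`), and for GSEA-like methods `nes`.
#' @param method `"ORA"` or `"GSEA"` (GSEA-like, score-based).
#' @param alpha significance level applied to the adjusted statistic.
#' @return nested list of nodes `{id, name, size, significant, color_value,
#'   children}`; serialize with [circlepack_json()].
#' @export
export_circlepack <- function(hierarchy, results, method = c("GSEA", "ORA"),
                              alpha = 0.05) {
  method <- match.arg(method)
  stat_col <- intersect(c("p_adj", "q_fdr"), names(results))
  if (!length(stat_col))
    pc_stop("results must contain an adjusted statistic column ",
            "('p_adj' or 'q_fdr')")
  stat_col <- stat_col[1L]
  res <- results[!duplicated(results$node_id), , drop = FALSE]
  rownames(res) <- res$node_id

  g <- hierarchy$graph
  nodes <- hierarchy$nodes
  rownames(nodes) <- nodes$node_id

  mk <- function(id) {
    sig <- FALSE; col <- NA_real_
    if (id %in% rownames(res)) {
      padj <- res[id, stat_col]
      sig <- is.finite(padj) && padj < alpha
      if (method == "GSEA" && sig && "nes" %in% names(res))
        col <- res[id, "nes"]
    }
    kids <- names(igraph::neighbors(g, id, mode = "in"))
    list(id = id,
         name = nodes[id, "name"],
         size = nodes[id, "size"],
         significant = sig,
         color_value = col,
         children = lapply(sort(kids), mk))
  }

  forest <- lapply(hierarchy$roots, mk)
  unmapped <- setdiff(res$node_id, nodes$node_id)
  if (length(unmapped)) {
    pc_warn(length(unmapped), " result row(s) for pathways absent from the ",
            "hierarchy attached under the 'unmapped' root")
    kids <- lapply(sort(unmapped), function(id) {
      padj <- res[id, stat_col]
      sig <- is.finite(padj) && padj < alpha
      col <- if (method == "GSEA" && sig && "nes" %in% names(res))
        res[id, "nes"] else NA_real_
      list(id = id, name = id, size = 0L, significant = sig,
           color_value = col, children = list())
    })
    forest <- c(forest, list(list(id = "unmapped", name = "unmapped",
                                  size = 0L, significant = FALSE,
                                  color_value = NA_real_, children = kids)))
  }
  forest
}

#' Serialize a circle-pack forest as nested JSON
#'
#' @param forest output of [export_circlepack()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
circlepack_json <- function(forest, path = NULL) {
  js <- jsonlite::toJSON(forest, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
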