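#' Collapse equivalent pathways into meta-pathway groups
#'
#' Pathways in different databases that represent the same biological
#' pathway are linked by `equivalentTo` mapping records. Equivalence is
#' taken as a true equivalence relation: groups are the connected components
#' of the graph whose edges are the `equivalentTo` records, so two pathways
#' never directly mapped still merge when linked through a third
#' (A = B, B = C implies A = C). Each component becomes one group whose gene
#' set is the exact union of its members' genes. Pathways with no
#' equivalence record become singleton groups and retain their original
#' identifier; merged (multi-member) groups receive fresh `"DC:"`-prefixed
#' identifiers, numbered after sorting components by their smallest member
#' id so the scheme is stable under input order.
#'
#' Mapping records that reference a pathway absent from the supplied
#' collections are excluded with a warning; the excluded rows are attached
#' as the `"report"` attribute of the result.
#'
#' @param mappings mapping records ([read_mapping_table()]); only
#'   `equivalentTo` rows are used here.
#' @param collections list of [gene_set_collection()] objects.
#' @return list of `equivalence_group` objects (fields `group_id`,
#'   `group_name`, `members` data.frame, `member_genes` named list and
#'   `genes`, the merged union), with attribute `report` (excluded mapping
#'   rows, possibly empty).
#' @export
build_equivalence_groups <- function(mappings, collections) {
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  names(collections) <- vapply(collections, `[[`, character(1), "database")

  keys <- character(0); genes_by_key <- list()
  name_by_key <- character(0); db_by_key <- character(0)
  id_by_key <- character(0)
  for (cl in collections) {
    for (s in cl$sets) {
      k <- pc_key(cl$database, s$set_id)
      keys <- c(keys, k)
      genes_by_key[[k]] <- s$genes
      name_by_key[k] <- s$name
      db_by_key[k] <- cl$database
      id_by_key[k] <- s$set_id
    }
  }

  eq <- mappings[mappings$relation == "equivalentTo", , drop = FALSE]
  src <- pc_key(eq$source_db, eq$source_id)
  tgt <- pc_key(eq$target_db, eq$target_id)
  known <- src %in% keys & tgt %in% keys
  report <- eq[!known, , drop = FALSE]
  if (nrow(report))
    pc_warn(nrow(report), " equivalentTo mapping(s) reference pathways ",
            "absent from the supplied collections; excluded (see report)")
  src <- src[known]; tgt <- tgt[known]

  ## connected components over all known pathways (isolated = singleton)
  g <- igraph::graph_from_data_frame(
    data.frame(from = src, to = tgt, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = keys, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  members_by_comp <- split(names(comp), comp)
  ## order members within a component, and components among themselves,
  ## by smallest member id so group numbering is input-order stable
  members_by_comp <- lapply(members_by_comp, function(m)
    m[order(id_by_key[m], db_by_key[m])])
  members_by_comp <- members_by_comp[order(vapply(
    members_by_comp, function(m) id_by_key[m[1L]], character(1)))]

  multi <- vapply(members_by_comp, length, integer(1)) > 1L
  dc_ids <- character(length(members_by_comp))
  dc_ids[multi] <- sprintf("DC:%04d", seq_len(sum(multi)))
  dc_ids[!multi] <- vapply(members_by_comp[!multi],
                           function(m) id_by_key[m[1L]], character(1))

  groups <- vector("list", length(members_by_comp))
  for (i in seq_along(members_by_comp)) {
    m <- members_by_comp[[i]]
    mg <- genes_by_key[m]
    names(mg) <- m
    groups[[i]] <- structure(list(
      group_id = dc_ids[i],
      group_name = unname(name_by_key[m[1L]]),
      members = data.frame(database = unname(db_by_key[m]),
                           set_id = unname(id_by_key[m]),
                           stringsAsFactors = FALSE),
      member_genes = mg,
      genes = sort(unique(unlist(mg, use.names = FALSE)))),
      class = "equivalence_group")
  }
  names(groups) <- dc_ids
  attr(groups, "report") <- report
  groups
}

#' @export
print.equivalence_group <- function(x, ...) {
  cat(sprintf("equivalence_group %s ('%s'): %d member(s) in {%s}, %d genes\n",
              x$group_id, x$group_name, nrow(x$members),
              paste(unique(x$members$database), collapse = ", "),
              length(x$genes)))
  invisible(x)
}

#' Export the merged meta-database
#'
#' One gene set per equivalence group (id = group id, genes = merged
#' union), forming the meta-database that is analyzed alongside the source
#' databases. Writable with [write_gmt()].
#'
#' @param groups output of [build_equivalence_groups()].
#' @param database label for the meta-collection.
#' @return a [gene_set_collection()].
#' @export
export_meta_collection <- function(groups, database = "META") {
  gene_set_collection(database, lapply(groups, function(g)
    gene_set(g$group_id, g$group_name, g$genes)))
}

#' Look up the equivalence group containing a database pathway
#'
#' @param groups output of [build_equivalence_groups()].
#' @param set_id pathway identifier within `database`.
#' @param database database label.
#' @return the group id, or `NA` if the pathway is unknown.
#' @export
group_for_set <- function(groups, set_id, database) {
  idx <- group_index(groups)
  unname(idx[pc_key(database, set_id)])
}

## index: (database, set_id) key -> group_id
group_index <- function(groups) {
  idx <- character(0)
  for (g in groups) {
    k <- pc_key(g$members$database, g$members$set_id)
    idx[k] <- g$group_id
  }
  idx
}
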