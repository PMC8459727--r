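#' Gene-set collections and the GMT exchange format
#'
#' A gene-set collection is a named pathway database: a list of gene sets,
#' each holding HGNC symbols. GMT is the tab-separated exchange format used
#' throughout (one set per line: identifier, description/name, then member
#' genes).
#'
#' @param database single non-empty string labelling the collection
#'   (e.g. `"KEGG"`, `"Reactome"`).
#' @param sets list of gene sets as returned by [gene_set()].
#' @return An object of class `gene_set_collection`: a list with elements
#'   `database` and `sets` (a list named by set identifier).
#' @seealso [read_gmt()], [write_gmt()]
#' @export
gene_set_collection <- function(database, sets = list()) {
  if (!is.character(database) || length(database) != 1L || !nzchar(database))
    pc_stop("'database' must be a single non-empty string")
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids))
    pc_stop("duplicate set_id in collection '", database, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, function(s) { s$database <- database; s })
  names(sets) <- ids
  structure(list(database = database, sets = sets),
            class = "gene_set_collection")
}

#' @rdname gene_set_collection
#' @param set_id opaque identifier, unique within its collection.
#' @param name display name.
#' @param genes character vector of HGNC symbols; normalized
#'   (uppercased, de-duplicated) on construction. Must be non-empty.
#' @export
gene_set <- function(set_id, name, genes, database = NA_character_) {
  if (!nzchar(set_id)) pc_stop("gene set identifier must be non-empty")
  genes <- unique(normalize_symbols(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    pc_stop("gene set '", set_id, "' has no genes")
  structure(list(set_id = set_id, name = name, database = database,
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, %d distinct genes\n",
              x$database, length(x$sets),
              length(unique(unlist(lapply(x$sets, `[[`, "genes"))))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Union of all genes in one or more collections
#'
#' @param ... `gene_set_collection` objects (or a single list of them).
#' @return character vector of distinct normalized symbols.
#' @export
collection_universe <- function(...) {
  colls <- list(...)
  if (length(colls) == 1L && !inherits(colls[[1L]], "gene_set_collection"))
    colls <- colls[[1L]]
  sort(unique(unlist(lapply(colls, function(cl)
    unlist(lapply(cl$sets, `[[`, "genes"), use.names = FALSE)))))
}

#' Read a GMT gene-set file
#'
#' Each line must have at least three tab-separated fields: set identifier,
#' description, then one gene per field. Gene symbols are uppercased and
#' de-duplicated; empty gene fields are dropped. Structurally invalid lines
#' are rejected (never silently repaired), with the offending line number in
#' the error message.
#'
#' @param path path to a GMT file.
#' @param database collection label; defaults to the file name without
#'   extension.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, database = NULL) {
  if (!file.exists(path)) pc_stop("GMT file not found: ", path)
  if (is.null(database))
    database <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      pc_stop("malformed GMT line ", i, " in '", path,
              "': expected >= 3 tab-separated fields, got ", length(fields))
    sets[[i]] <- gene_set(fields[[1L]], fields[[2L]], fields[-(1:2)])
  }
  ids <- vapply(sets, `[[`, character(1), "set_id")
  if (anyDuplicated(ids))
    pc_stop("duplicate set_id in '", path, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene_set_collection(database, sets)
}

#' Write a collection to a GMT file
#'
#' Round-trips through [read_gmt()] up to gene order. Identifiers or names
#' containing the tab delimiter are rejected rather than sanitized.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    if (grepl("\t", s$set_id, fixed = TRUE) ||
        grepl("\t", s$name, fixed = TRUE))
      pc_stop("set '", s$set_id, "': tab is the GMT field delimiter and may ",
              "not appear in identifiers or names")
    paste(c(s$set_id, s$name, s$genes), collapse = "\t")
  }, character(1))
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) pc_stop("cannot write GMT file: ", path, class = "pc_io_error")
  invisible(path)
}
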