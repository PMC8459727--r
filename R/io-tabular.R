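MAPPING_COLUMNS <- c("source_db", "source_id", "source_name",
                     "relation", "target_db", "target_id", "target_name")
MAPPING_RELATIONS <- c("equivalentTo", "isPartOf")

#' Read a pathway mapping table
#'
#' The mapping table links pathways across databases. It is a 7-column TSV
#' with header `source_db, source_id, source_name, relation, target_db,
#' target_id, target_name`, where `relation` is `equivalentTo` (the two
#' pathways represent the same biological pathway and are merged) or
#' `isPartOf` (the source pathway is a part of the target pathway or
#' category; these rows build the hierarchy). The curated mapping resource
#' published alongside the four default databases is distributed as an Excel
#' workbook; export it to this TSV dialect once (e.g.
#' `python -c "import pandas; pandas.read_excel('mapping.xlsx').to_csv('mapping.tsv', sep='\t', index=False)"`)
#' and use the TSV here.
#'
#' @param path path to the TSV file (header row required).
#' @return `data.frame` of validated mapping records.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) pc_stop("mapping file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(MAPPING_COLUMNS, names(df))
  if (length(missing))
    pc_stop("mapping file '", path, "' is missing column(s): ",
            paste(missing, collapse = ", "))
  df <- df[MAPPING_COLUMNS]
  bad <- which(!df$relation %in% MAPPING_RELATIONS)
  if (length(bad))
    pc_stop("unknown relation '", df$relation[bad[1L]], "' in mapping row ",
            bad[1L], " (+", length(bad) - 1L, " more); allowed: ",
            paste(MAPPING_RELATIONS, collapse = ", "))
  empty <- which(!nzchar(df$source_id) | !nzchar(df$target_id))
  if (length(empty))
    pc_stop("empty pathway identifier in mapping row(s): ",
            paste(utils::head(empty, 5L), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write mapping records to TSV
#' @param mappings mapping `data.frame` as from [read_mapping_table()].
#' @param path output path.
#' @export
write_mapping_table <- function(mappings, path) {
  utils::write.table(mappings[MAPPING_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group expression dataset
#'
#' Couples a genes x samples matrix of finite continuous values (e.g.
#' log-scale normalized expression) with a two-class sample design. Exactly
#' two classes must be present, each with at least two samples. Duplicate
#' gene rows are collapsed to the row with maximum mean expression (a common
#' preprocessing convention for rank-based enrichment), with a message.
#'
#' @param values numeric matrix, rows named by HGNC symbol, columns by
#'   sample id.
#' @param labels named character vector or 2-column data.frame
#'   (sample, class) assigning every sample to one of two classes.
#' @return an `expression_dataset` object. The `classes` element records the
#'   two class labels in order of first appearance in the design; the first
#'   is treated as the "A" (positive) class by [rank_genes()].
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    pc_stop("'values' must be a numeric matrix")
  if (any(!is.finite(values)))
    pc_stop("expression matrix contains non-finite values")
  if (is.data.frame(labels)) {
    lab <- as.character(labels[[2L]])
    names(lab) <- as.character(labels[[1L]])
    labels <- lab
  }
  if (is.null(rownames(values)) || is.null(colnames(values)))
    pc_stop("expression matrix must have gene row names and sample column names")
  rownames(values) <- normalize_symbols(rownames(values))
  unlabeled <- setdiff(colnames(values), names(labels))
  if (length(unlabeled))
    pc_stop("sample(s) in expression matrix missing from design: ",
            paste(unlabeled, collapse = ", "))
  labels <- labels[colnames(values)]
  classes <- unique(unname(labels))
  if (length(classes) != 2L)
    pc_stop("design must define exactly two classes, found ",
            length(classes), ": ", paste(classes, collapse = ", "))
  if (any(table(labels) < 2L))
    pc_stop("each class needs >= 2 samples")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    message("collapsing ", length(dup),
            " duplicated gene row(s) by maximum mean expression")
    keep <- !logical(nrow(values))
    rm <- rowMeans(values)
    for (g in dup) {
      idx <- which(rownames(values) == g)
      keep[idx[-which.max(rm[idx])]] <- FALSE
    }
    values <- values[keep, , drop = FALSE]
  }
  structure(list(values = values, labels = labels, classes = classes),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("expression_dataset: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Ranked gene list
#'
#' Ordered (gene, score) pairs for pre-ranked enrichment. Genes must be
#' unique and scores finite; the list is ordered by descending score with
#' ties broken by ascending symbol so that downstream enrichment scores are
#' deterministic.
#'
#' @param gene character vector of HGNC symbols.
#' @param score numeric vector of finite ranking scores.
#' @return a `ranked_list`: data.frame with columns `gene`, `score`.
#' @export
ranked_list <- function(gene, score) {
  gene <- normalize_symbols(gene)
  if (anyDuplicated(gene))
    pc_stop("duplicate gene in ranked list: ",
            paste(unique(gene[duplicated(gene)]), collapse = ", "))
  score <- as.numeric(score)
  if (any(!is.finite(score))) pc_stop("ranked-list scores must be finite")
  ord <- order(-score, gene)
  structure(data.frame(gene = gene[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Differential-expression results table
#'
#' Consumed (not computed) for gene-level annotation: per-gene log2 fold
#' change and adjusted p-value as produced by any upstream DGE tool.
#'
#' @param gene,log2fc,p_adj parallel vectors; `p_adj` in `[0, 1]`,
#'   `log2fc` finite, genes unique.
#' @return a `dge_table`: data.frame with columns `gene`, `log2fc`, `p_adj`.
#' @export
dge_table <- function(gene, log2fc, p_adj) {
  gene <- normalize_symbols(gene)
  if (anyDuplicated(gene))
    pc_stop("duplicate gene in DGE table: ",
            paste(unique(gene[duplicated(gene)]), collapse = ", "))
  log2fc <- as.numeric(log2fc); p_adj <- as.numeric(p_adj)
  if (any(!is.finite(log2fc))) pc_stop("log2fc must be finite")
  if (any(is.na(p_adj) | p_adj < 0 | p_adj > 1))
    pc_stop("adjusted p-values must lie in [0, 1]")
  structure(data.frame(gene = gene, log2fc = log2fc, p_adj = p_adj,
                       stringsAsFactors = FALSE),
            class = c("dge_table", "data.frame"))
}

#' Read one of the tabular input files
#'
#' Dispatches on `kind`:
#' \describe{
#'   \item{`gene_list`}{plain text, one HGNC symbol per line (no header);
#'     returns a character vector of unique normalized symbols.}
#'   \item{`rnk`}{two tab-separated columns gene, score (no header);
#'     returns a [ranked_list()]. Duplicate genes are an error.}
#'   \item{`expression`}{TSV, header row; first column gene symbol, the
#'     remaining columns one sample each; returns a numeric matrix.
#'     Non-numeric cells are an error.}
#'   \item{`design`}{TSV with header `sample, class`; returns a named
#'     character vector sample -> class.}
#'   \item{`dge`}{TSV with header `gene, log2fc, padj` (or `p_adj`);
#'     returns a [dge_table()].}
#' }
#' Use [read_expression_dataset()] to read and cross-validate an expression
#' matrix together with its design.
#'
#' @param path input file path (UTF-8).
#' @param kind one of `"gene_list"`, `"rnk"`, `"expression"`, `"design"`,
#'   `"dge"`.
#' @return see Details.
#' @export
read_tabular_inputs <- function(path,
                                kind = c("gene_list", "rnk", "expression",
                                         "design", "dge")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pc_stop(kind, " file not found: ", path)
  switch(kind,
    gene_list = {
      x <- trimws(readLines(path, encoding = "UTF-8"))
      unique(normalize_symbols(x[nzchar(x)]))
    },
    rnk = {
      df <- utils::read.delim(path, header = FALSE, sep = "\t",
                              quote = "", fileEncoding = "UTF-8")
      if (ncol(df) != 2L)
        pc_stop(".rnk file must have exactly 2 tab-separated columns, got ",
                ncol(df))
      if (!is.numeric(df[[2L]]))
        pc_stop("non-numeric score in .rnk file '", path, "'")
      ranked_list(df[[1L]], df[[2L]])
    },
    expression = {
      df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                              check.names = FALSE, fileEncoding = "UTF-8")
      if (ncol(df) < 3L)
        pc_stop("expression TSV needs a gene column plus >= 2 sample columns")
      for (j in 2:ncol(df))
        if (!is.numeric(df[[j]]))
          pc_stop("non-numeric expression value in column '",
                  names(df)[j], "'")
      m <- as.matrix(df[-1L])
      rownames(m) <- as.character(df[[1L]])
      m
    },
    design = {
      df <- utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = "character", quote = "",
                              fileEncoding = "UTF-8")
      if (ncol(df) < 2L)
        pc_stop("design TSV needs columns: sample, class")
      stats::setNames(df[[2L]], df[[1L]])
    },
    dge = {
      df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                              fileEncoding = "UTF-8")
      names(df) <- tolower(names(df))
      pcol <- intersect(c("p_adj", "padj"), names(df))
      if (!all(c("gene", "log2fc") %in% names(df)) || !length(pcol))
        pc_stop("DGE TSV needs columns: gene, log2fc, padj")
      dge_table(df$gene, df$log2fc, df[[pcol[1L]]])
    })
}

#' Read an expression matrix with its two-class design
#'
#' Reads both files via [read_tabular_inputs()] and cross-checks them
#' (every sample labeled, exactly two classes, each with >= 2 samples).
#'
#' @param expression_path expression TSV path.
#' @param design_path design TSV path.
#' @return an [expression_dataset()].
#' @export
read_expression_dataset <- function(expression_path, design_path) {
  expression_dataset(read_tabular_inputs(expression_path, "expression"),
                     read_tabular_inputs(design_path, "design"))
}
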