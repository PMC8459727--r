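#' Normalize HGNC gene symbols
#'
#' Trims surrounding whitespace and uppercases. No alias resolution is
#' attempted: symbols are taken as given, and out-of-vocabulary symbols are
#' kept rather than dropped. The operation is idempotent.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c(" tp53", "BRCA1 "))
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## Validation errors get their own condition class so the CLI can map them
## to exit code 2 while unexpected failures map to 3.
pc_stop <- function(..., class = "pc_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

pc_warn <- function(...) warning(paste0(...), call. = FALSE)

## key used to index pathways by (database, set_id)
pc_key <- function(database, set_id) paste(database, set_id, sep = "||")

#' @keywords internal
"_PACKAGE"
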