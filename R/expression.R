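#' Read a normalized expression matrix from TSV
#'
#' Expects genes in rows and samples in columns: the first column holds gene
#' identifiers, the header row holds sample identifiers, and the body is
#' numeric (normalized expression units). Identifiers are opaque,
#' case-sensitive strings.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x samples) with gene IDs as rownames and
#'   sample IDs as colnames. The attribute `"zero_variance"` carries the IDs
#'   of genes whose expression is constant across samples; such genes cannot
#'   enter correlation-based tests and are excluded upstream by
#'   [expand_gene()].
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 2L) stop("expression matrix needs at least one sample column", call. = FALSE)
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                 body[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, colnames(body))
  v <- apply(values, 1L, stats::var)
  attr(values, "zero_variance") <- gene_ids[v == 0]
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: genes in rows, first column `gene`,
#' header row of sample IDs. Values are written with full precision so a
#' write/read cycle is lossless.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param header Optional character vector of comment lines (without the
#'   leading `#`) written before the table, e.g. provenance from the CLI.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, header = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con, sep = "\n")
  }
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con, sep = "\n")
  body <- apply(mat, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a gene annotation table
#'
#' A tab-separated table with columns `v1_id` (primary identifier, unique),
#' and optionally `vcost_id`, `symbol` and `category` (functional category
#' code, e.g. a `vv60`-prefixed code for transcription factors). Genes absent
#' from the table keep their raw ID with empty symbol/category downstream.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `v1_id`, `vcost_id`, `symbol`,
#'   `category` (missing optional columns are filled with `NA`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (!"v1_id" %in% names(ann)) stop("annotation table must have a 'v1_id' column", call. = FALSE)
  if (anyDuplicated(ann$v1_id)) stop("duplicate v1_id in annotation table", call. = FALSE)
  for (col in c("vcost_id", "symbol", "category")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  ann[, c("v1_id", "vcost_id", "symbol", "category")]
}
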