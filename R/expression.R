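#' Construct an expression matrix
#'
#' Light wrapper that validates a genes-by-conditions numeric matrix for use
#' throughout the pipeline. Row identifiers are probe or gene ids, column
#' identifiers are condition ids; values are intensity-like and must be
#' finite (no imputation is performed anywhere downstream, the mutual
#' information estimator assumes complete rows).
#'
#' @param values numeric matrix, rows = probes or genes, columns = conditions.
#' @param level `"probe"` or `"gene"`; stored as an attribute and checked by
#'   [collapse_probes()].
#' @return the validated matrix with a `level` attribute.
#' @export
expression_matrix <- function(values, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("row and column identifiers are required")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("row and column identifiers must be unique")
  if (any(!is.finite(values)))
    stop("expression values must be finite; missing values are rejected at load time")
  attr(values, "level") <- level
  values
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (condition) onto the same empirical distribution: the
#' mean of the sorted columns. Within-column rank order is preserved; tied
#' values receive the mean of the normalized values at their tied ranks.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param matrix numeric genes/probes-by-conditions matrix (see
#'   [expression_matrix()]).
#' @return matrix of the same shape and dimnames, quantile-normalized.
#' @examples
#' m <- cbind(a = c(5, 2, 3), b = c(4, 1, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (ncol(matrix) < 2L)
    stop("quantile normalization needs at least 2 columns")
  if (any(!is.finite(matrix)))
    stop("non-finite values in expression matrix")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  attr(out, "level") <- attr(matrix, "level")
  out
}

#' Collapse probe-level rows to gene level
#'
#' Averages all retained probes of the same gene (arithmetic mean per
#' condition). Control probes and probes without a gene symbol are dropped
#' before averaging. No probe-level significance filter is applied: every
#' retained annotated probe of a gene contributes equally (a different
#' notion of "redundant probes" can be emulated by pre-filtering the
#' annotation).
#'
#' @param matrix probe-level expression matrix.
#' @param annotation data frame with columns `probe_id`, `gene_symbol`
#'   (`NA` or `""` means unannotated) and optionally logical `is_control`.
#' @return gene-level expression matrix (`level` attribute `"gene"`), rows
#'   ordered by gene symbol.
#' @export
collapse_probes <- function(matrix, annotation) {
  if (!identical(attr(matrix, "level"), "probe"))
    stop("`matrix` must be at probe level")
  req <- c("probe_id", "gene_symbol")
  if (!all(req %in% names(annotation)))
    stop("annotation needs columns probe_id and gene_symbol")
  if (anyDuplicated(annotation$probe_id))
    stop("each probe may map to at most one gene symbol")
  ann <- annotation
  if (is.null(ann$is_control)) ann$is_control <- FALSE
  ann$gene_symbol <- as.character(ann$gene_symbol)
  keep <- !ann$is_control & !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)
  ann <- ann[keep, , drop = FALSE]
  ann <- ann[ann$probe_id %in% rownames(matrix), , drop = FALSE]
  if (nrow(ann) == 0L)
    stop("all probes were dropped (control or unannotated)")
  sub <- matrix[ann$probe_id, , drop = FALSE]
  grp <- factor(ann$gene_symbol)
  sums <- rowsum(sub, grp)
  out <- sums / as.vector(table(grp))
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(as.matrix(out), level = "gene")
}

#' Read / write the expression TSV dialect
#'
#' Tab-separated, UTF-8, decimal point: header row of condition ids, first
#' column the row (gene or probe) identifier.
#'
#' @param path file path.
#' @param level row level recorded on the returned matrix.
#' @return `read_expression_tsv()` returns a numeric matrix with a `level`
#'   attribute; `write_expression_tsv()` invisibly returns `path`.
#' @export
read_expression_tsv <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in expression file: ", path)
  rownames(m) <- ids
  expression_matrix(m, level = level)
}

#' @rdname read_expression_tsv
#' @param matrix matrix to write.
#' @param id_column header of the identifier column.
#' @export
write_expression_tsv <- function(matrix, path, id_column = "gene") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
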