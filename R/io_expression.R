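#' Construct a validated expression matrix
#'
#' @param tpm Numeric matrix of TPM values, genes in rows (rownames = gene
#'   ids), tissues in columns (colnames = tissue ids).
#' @param replicate_map Optional data frame with columns `sample` and
#'   `tissue`, recording the sample-to-tissue aggregation that produced the
#'   matrix.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(tpm, replicate_map = NULL) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("expression matrix needs gene rownames and tissue colnames")
  }
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(tpm))) stop("duplicate tissue ids in matrix")
  if (ncol(tpm) < 2L) stop("expression matrix needs at least 2 tissues")
  if (any(!is.finite(tpm))) stop("non-finite TPM value in matrix")
  if (any(tpm < 0)) stop("negative TPM value in matrix")
  if (!is.null(replicate_map)) {
    stopifnot(all(c("sample", "tissue") %in% names(replicate_map)))
  }
  structure(list(tpm = tpm, replicate_map = replicate_map),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "tissues\n")
  invisible(x)
}

#' Read a TPM expression matrix and aggregate replicates per tissue
#'
#' The file is a TSV with a header row of sample ids and one row per gene
#' (gene id in the first column). Every sample column must be mapped to a
#' tissue by `replicate_map`; replicate columns of one tissue are aggregated
#' with the arithmetic mean (the Human Protein Atlas convention).
#'
#' @param path TSV file of TPM values.
#' @param replicate_map Data frame with columns `sample` and `tissue`, or a
#'   named character vector (names = samples, values = tissues).
#' @param aggregator Only `"mean"` is supported.
#' @return An `expr_matrix` of genes x tissues.
#' @export
read_expression <- function(path, replicate_map, aggregator = c("mean")) {
  aggregator <- match.arg(aggregator)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs a gene column plus samples")
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric TPM value in ", path)
  if (any(!is.finite(vals))) stop("non-finite TPM value in ", path)
  if (any(vals < 0)) stop("negative TPM value in ", path)
  rownames(vals) <- gene_ids

  if (is.data.frame(replicate_map)) {
    stopifnot(all(c("sample", "tissue") %in% names(replicate_map)))
    map <- stats::setNames(as.character(replicate_map$tissue),
                           as.character(replicate_map$sample))
  } else {
    map <- replicate_map
  }
  samples <- colnames(vals)
  unmapped <- setdiff(samples, names(map))
  if (length(unmapped)) {
    stop("sample(s) without tissue mapping: ", paste(unmapped, collapse = ", "))
  }
  tissues <- unique(unname(map[samples]))
  agg <- vapply(tissues, function(t) {
    cols <- samples[map[samples] == t]
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (!is.matrix(agg)) agg <- matrix(agg, nrow = nrow(vals),
                                     dimnames = list(gene_ids, tissues))
  colnames(agg) <- tissues
  expression_matrix(agg, replicate_map = data.frame(
    sample = samples, tissue = unname(map[samples]),
    stringsAsFactors = FALSE))
}

#' Write an expression matrix (or any gene-by-column table) as TSV
#'
#' @param x An `expr_matrix`, matrix, or data frame.
#' @param path Output path.
#' @param id_col Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  m <- if (inherits(x, "expr_matrix")) x$tpm else x
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
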