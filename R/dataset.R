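#' Labeled two-class expression dataset
#'
#' The central container: a genes-by-samples numeric matrix with gene
#' identifiers as row names, sample identifiers as column names, and a
#' two-level factor of per-sample class labels (microarray convention:
#' genes are rows).
#'
#' @param matrix Numeric genes-by-samples matrix.
#' @param gene_ids Character vector of unique gene identifiers, one per row
#'   (defaults to the matrix row names).
#' @param labels Per-sample class tags with exactly two distinct classes.
#' @param sample_ids Optional sample identifiers (default: column names, or
#'   `sample1..n`).
#' @return An object of class `expr_dataset`.
#' @export
expression_dataset <- function(matrix, gene_ids = rownames(matrix), labels,
                               sample_ids = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(matrix)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(matrix)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(matrix)) {
    stop("gene_ids length must equal the matrix row count", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) != ncol(matrix)) {
    stop("labels length must equal the matrix column count", call. = FALSE)
  }
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) {
    stop("expected exactly two classes, found ", nlevels(labels), ": ",
         paste(levels(labels), collapse = ", "), call. = FALSE)
  }
  rownames(matrix) <- gene_ids
  colnames(matrix) <- sample_ids
  structure(
    list(matrix = matrix, gene_ids = gene_ids, labels = labels,
         sample_ids = sample_ids),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("expression dataset: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$matrix)

#' Read / write an expression matrix with sample labels
#'
#' The on-disk format is a pair of tab-separated files: the matrix file has
#' a `gene_id` first column, a header of sample identifiers, and a numeric
#' body; the labels file has columns `sample_id` and `class`. Samples are
#' aligned between the two files by identifier, not by order, so a permuted
#' labels file yields the identical dataset.
#'
#' @param matrix_path,labels_path Paths of the two TSV files.
#' @param data An `expr_dataset` to write.
#' @return `read_expression()` returns an [expression_dataset()];
#'   `write_expression()` returns the paths invisibly.
#' @export
read_expression <- function(matrix_path, labels_path) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              colClasses = c("character"))
  if (ncol(mat_df) < 2L) stop("matrix file needs gene ids plus at least one sample",
                              call. = FALSE)
  gene_ids <- mat_df[[1L]]
  body <- as.matrix(mat_df[, -1L, drop = FALSE])
  suppressWarnings(num <- apply(body, 2L, as.numeric))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at gene '", gene_ids[bad[["row"]]],
         "', sample '", colnames(body)[bad[["col"]]], "'", call. = FALSE)
  }
  num <- matrix(num, nrow = length(gene_ids),
                dimnames = list(gene_ids, colnames(body)))

  lab_df <- utils::read.delim(labels_path, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(lab_df))) {
    stop("labels file must have columns 'sample_id' and 'class'", call. = FALSE)
  }
  missing <- setdiff(colnames(num), lab_df$sample_id)
  if (length(missing)) {
    stop("samples missing from labels file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- lab_df$class[match(colnames(num), lab_df$sample_id)]
  expression_dataset(num, gene_ids, labels)
}

#' @rdname read_expression
#' @export
write_expression <- function(data, matrix_path, labels_path) {
  stopifnot(inherits(data, "expr_dataset"))
  out <- data.frame(gene_id = data$gene_ids, data$matrix,
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample_id = data$sample_ids,
                    class = as.character(data$labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, labels_path))
}
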