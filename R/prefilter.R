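#' Per-gene z-score normalization
#'
#' Transforms every gene row to mean 0 and unit standard deviation across
#' samples, removing scale differences between genes before ranking and
#' classification. Zero-variance rows (constant genes) map to all zeros
#' rather than dividing by zero. Normalization is applied once to the full
#' dataset, before prefiltering and before LOOCV.
#'
#' @param data An [expression_dataset()].
#' @return A normalized `expr_dataset` of the same shape.
#' @export
normalize_expression <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  m <- data$matrix
  if (any(!is.finite(m))) stop("expression matrix must be finite", call. = FALSE)
  mu <- rowMeans(m)
  centered <- m - mu
  sd <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  scale <- ifelse(sd > 0, sd, 1)
  z <- centered / scale
  z[sd == 0, ] <- 0
  expression_dataset(z, data$gene_ids, data$labels, data$sample_ids)
}

#' Rank genes by two-sample t-test
#'
#' Computes a pooled-variance (Student) two-sample t statistic and two-sided
#' p-value per gene, comparing the two classes, and orders the genes by
#' ascending p-value; ties are broken by original gene index so rankings are
#' deterministic. `var_equal = FALSE` switches to the Welch test. A gene
#' with zero pooled variance scores p = 1 when the class means agree and
#' p = 0 when they differ (perfect separation).
#'
#' @param data An [expression_dataset()] with at least two samples per class.
#' @param var_equal Pooled-variance test when `TRUE` (default), Welch
#'   otherwise.
#' @return A `gene_ranking` data frame with columns `gene_id`,
#'   `t_statistic`, `p_value`, and `rank`, sorted by ascending p-value.
#' @export
t_test_rank <- function(data, var_equal = TRUE) {
  stopifnot(inherits(data, "expr_dataset"))
  g1 <- data$labels == levels(data$labels)[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs at least two samples for the t-test", call. = FALSE)
  }
  x1 <- data$matrix[, g1, drop = FALSE]
  x2 <- data$matrix[, !g1, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, nrow(data$matrix))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  diff <- m1 - m2
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              ifelse(t_stat == 0, 1, 0))
  p[se == 0 & diff == 0] <- 1
  ord <- order(p, seq_along(p))
  ranking <- data.frame(
    gene_id = data$gene_ids[ord],
    t_statistic = t_stat[ord],
    p_value = p[ord],
    rank = seq_along(ord),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(ranking) <- c("gene_ranking", "data.frame")
  ranking
}

#' Keep the top-ranked genes
#'
#' Returns the identifiers of the `k` genes with the smallest t-test
#' p-values, in rank order; the default `k = 50` fixes the particle length
#' of the downstream search. When `k` exceeds the gene count, all genes are
#' returned.
#'
#' @param ranking A `gene_ranking` from [t_test_rank()].
#' @param k Positive number of genes to keep.
#' @return Character vector of at most `k` gene identifiers.
#' @export
select_top_k <- function(ranking, k = 50L) {
  stopifnot(inherits(ranking, "gene_ranking"), k >= 1L)
  utils::head(ranking$gene_id, k)
}

#' Export a gene ranking as TSV
#'
#' @param ranking A `gene_ranking`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
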