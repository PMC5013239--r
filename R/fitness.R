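#' Wrapper-fitness configuration
#'
#' `fitness_weights()` holds the weights of the composite wrapper objective
#' `score = accuracy_weight * accuracy + size_weight * reference_size / feature_number`,
#' with accuracy on the percent scale (0-100). The defaults 0.6 / 0.4 make
#' the classification accuracy dominate the subset-size reward; the
#' reference size 50 matches the default prefilter width, so a subset using
#' all 50 candidate genes earns exactly `size_weight` from the size term.
#'
#' `svm_config()` fixes the wrapped classifier: a radial-basis-function SVM
#' with cost 1 and, unless overridden, the kernel width rule
#' `gamma = 1 / (number of selected features)` — the long-standing libsvm
#' defaults. Feature columns are not rescaled inside the SVM; the pipeline
#' normalizes genes once up front.
#'
#' @param accuracy_weight,size_weight Non-negative weights of the accuracy
#'   and size terms.
#' @param reference_size Numerator of the size reward.
#' @param cost_C SVM soft-margin cost.
#' @param gamma Either `NULL` (the `1/features` rule) or an explicit
#'   positive kernel width.
#' @return A `fitness_weights` or `svm_config` list.
#' @export
fitness_weights <- function(accuracy_weight = 0.6, size_weight = 0.4,
                            reference_size = 50L) {
  stopifnot(accuracy_weight >= 0, size_weight >= 0, reference_size >= 1)
  structure(
    list(
      accuracy_weight = accuracy_weight,
      size_weight = size_weight,
      reference_size = as.integer(reference_size)
    ),
    class = "fitness_weights"
  )
}

#' @rdname fitness_weights
#' @export
svm_config <- function(cost_C = 1, gamma = NULL) {
  stopifnot(cost_C > 0, is.null(gamma) || gamma > 0)
  structure(list(kernel = "radial", cost_C = cost_C, gamma = gamma),
            class = "svm_config")
}

#' Leave-one-out cross-validated SVM accuracy
#'
#' Trains one SVM per sample on the remaining `n - 1` samples and predicts
#' the held-out sample, cycling until every sample has served as the test
#' case; returns `100 * correct / n`. The procedure is deterministic given
#' the data and configuration. A training fold that contains a single class
#' (possible under heavy imbalance) predicts that sole class rather than
#' failing, so LOOCV is total.
#'
#' @param x Numeric samples-by-features matrix restricted to the candidate
#'   gene subset (at least one column).
#' @param labels Two-level factor (or coercible) of per-sample classes.
#' @param config An [svm_config()].
#' @return LOOCV accuracy as a percent in \[0, 100\], always a multiple of
#'   `100 / n`.
#' @export
loocv_accuracy <- function(x, labels, config = svm_config()) {
  x <- as.matrix(x)
  labels <- factor(labels)
  n <- nrow(x)
  stopifnot(n >= 2L, ncol(x) >= 1L, length(labels) == n,
            nlevels(labels) == 2L)
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  correct <- 0L
  for (i in seq_len(n)) {
    y_train <- droplevels(labels[-i])
    if (nlevels(y_train) == 1L) {
      pred <- levels(y_train)
    } else {
      fit <- e1071::svm(
        x[-i, , drop = FALSE], y_train,
        type = "C-classification", kernel = "radial",
        cost = config$cost_C, gamma = gamma, scale = FALSE
      )
      pred <- as.character(predict(fit, x[i, , drop = FALSE]))
    }
    if (pred == as.character(labels[i])) correct <- correct + 1L
  }
  100 * correct / n
}

#' Composite subset fitness
#'
#' Combines LOOCV accuracy (percent) with a subset-size reward:
#' `accuracy_weight * accuracy + size_weight * reference_size / feature_number`.
#' Strictly increasing in accuracy and strictly decreasing in subset size,
#' so among equally accurate subsets the smaller one always scores higher.
#'
#' @param accuracy Percent accuracy in \[0, 100\].
#' @param feature_number Positive number of selected genes.
#' @param weights A [fitness_weights()].
#' @return A numeric score.
#' @examples
#' subset_fitness(100, 10) # 62
#' @export
subset_fitness <- function(accuracy, feature_number, weights = fitness_weights()) {
  stopifnot(accuracy >= 0, accuracy <= 100)
  if (feature_number < 1) {
    stop("subset_fitness requires at least one selected feature", call. = FALSE)
  }
  weights$accuracy_weight * accuracy +
    weights$size_weight * weights$reference_size / feature_number
}

#' Evaluate a particle position on a labeled expression dataset
#'
#' Restricts the expression matrix to the genes whose bits are 1, scores
#' the subset with [loocv_accuracy()], and combines accuracy and subset
#' size via [subset_fitness()]. The all-zero position carries no genes and
#' returns the sentinel score `-Inf` (with accuracy recorded as 0), so it
#' can never displace a non-empty subset as a personal or global best.
#'
#' @param position A bitstring whose length equals the dataset's gene count.
#' @param data A [expression_dataset()].
#' @param weights A [fitness_weights()].
#' @param config An [svm_config()].
#' @param cache Optional environment used to memoize scores by position;
#'   the SVM fit is deterministic, so cached and fresh values coincide.
#' @return A `fitness_value` list with fields `accuracy` (percent),
#'   `feature_number`, and `score`.
#' @export
evaluate_particle <- function(position, data, weights = fitness_weights(),
                              config = svm_config(), cache = NULL) {
  position <- as_bits(position)
  stopifnot(inherits(data, "expr_dataset"))
  if (length(position) != nrow(data$matrix)) {
    stop(
      "position length ", length(position), " does not match gene count ",
      nrow(data$matrix),
      call. = FALSE
    )
  }
  key <- if (!is.null(cache)) bits_to_string(position)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])

  k <- sum(position)
  value <- if (k == 0L) {
    structure(list(accuracy = 0, feature_number = 0L, score = -Inf),
              class = "fitness_value")
  } else {
    acc <- loocv_accuracy(t(data$matrix[position == 1L, , drop = FALSE]),
                          data$labels, config)
    structure(
      list(accuracy = acc, feature_number = k,
           score = subset_fitness(acc, k, weights)),
      class = "fitness_value"
    )
  }
  if (!is.null(cache)) cache[[key]] <- value
  value
}
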