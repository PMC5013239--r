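#' Simulate a two-class expression matrix with planted informative genes
#'
#' Generates the synthetic study condition used throughout the package's
#' tests and benchmarks: a genes-by-samples matrix of i.i.d. Gaussian noise
#' in which a chosen number of informative genes carry a class-dependent
#' mean shift. Informative genes are drawn
#' `Normal(+effect_size * noise_sd / 2, noise_sd^2)` in class 1 and
#' `Normal(-effect_size * noise_sd / 2, noise_sd^2)` in class 2, so the
#' between-class mean difference is `effect_size` noise standard
#' deviations; all other genes are `Normal(0, noise_sd^2)` in both classes.
#' The informative rows are placed at random positions and returned as
#' ground truth. The generator is fully reproducible from its seed and
#' restores the caller's random stream.
#'
#' @param n_per_class Integer pair: samples in class 1 and class 2
#'   (imbalance, e.g. `c(22, 40)`, is supported).
#' @param n_genes Total number of genes.
#' @param n_informative Number of planted class-shifted genes
#'   (`<= n_genes`; 0 gives a pure-noise null dataset).
#' @param effect_size Class-mean difference in units of `noise_sd`.
#' @param noise_sd Positive noise standard deviation.
#' @param seed Integer seed.
#' @return A list with elements `dataset` (an [expression_dataset()] with
#'   classes `"class1"`/`"class2"`) and `informative_genes` (character
#'   vector of the planted gene identifiers).
#' @examples
#' sim <- simulate_expression(n_per_class = c(5, 5), n_genes = 20,
#'                            n_informative = 2, effect_size = 3, seed = 7)
#' sim$informative_genes
#' @export
simulate_expression <- function(n_per_class = c(20L, 20L), n_genes = 500L,
                                n_informative = 5L, effect_size = 2,
                                noise_sd = 1, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(
    length(n_per_class) == 2L, all(n_per_class >= 1L),
    n_genes >= 1L, n_informative >= 0L, n_informative <= n_genes,
    noise_sd > 0
  )
  n <- sum(n_per_class)
  with_local_seed(seed, {
    labels <- rep(c("class1", "class2"), n_per_class)
    m <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    informative <- sort(sample.int(n_genes, n_informative))
    if (n_informative > 0L) {
      shift <- effect_size * noise_sd / 2
      signs <- ifelse(labels == "class1", 1, -1)
      m[informative, ] <- m[informative, ] +
        rep(signs * shift, each = n_informative)
    }
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    sample_ids <- sprintf("sample%03d", seq_len(n))
    list(
      dataset = expression_dataset(m, gene_ids, labels, sample_ids),
      informative_genes = gene_ids[informative]
    )
  })
}
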