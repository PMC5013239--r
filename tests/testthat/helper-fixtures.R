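# Shared fixtures, all generated in code.

# Standard synthetic study condition: 40 samples, 500 genes, 5 planted
# informative genes at a 2-sd class-mean difference.
standard_sim <- function(seed = 11L) {
  simulate_expression(
    n_per_class = c(20L, 20L), n_genes = 500L, n_informative = 5L,
    effect_size = 2, noise_sd = 1, seed = seed
  )
}

# The same condition reduced to its t-test top-k search space, for fitness
# evaluations without re-running the prefilter in every test.
reduced_fixture <- function(seed = 11L, k = 50L) {
  sim <- standard_sim(seed)
  norm <- normalize_expression(sim$dataset)
  top <- select_top_k(t_test_rank(norm), k)
  list(
    data = expression_dataset(norm$matrix[top, , drop = FALSE], top,
                              norm$labels, norm$sample_ids),
    top = top,
    informative = sim$informative_genes
  )
}

# Tiny two-gene fixture with a wide class gap, for exact LOOCV checks.
blob_fixture <- function(n_per_class = 10L, gap = 5, sd = 0.2, seed = 42L) {
  n <- 2L * n_per_class
  set.seed(seed)
  m <- rbind(
    rnorm(n, mean = rep(c(-gap, gap), each = n_per_class), sd = sd),
    rnorm(n, mean = rep(c(gap, -gap), each = n_per_class), sd = sd)
  )
  expression_dataset(m, c("geneA", "geneB"),
                     rep(c("class1", "class2"), each = n_per_class))
}

# Small random dataset with no structure, for format and invariance checks.
noise_dataset <- function(n_genes = 30L, n_per_class = c(5L, 5L), seed = 7L) {
  set.seed(seed)
  n <- sum(n_per_class)
  expression_dataset(
    matrix(rnorm(n_genes * n), n_genes, n),
    sprintf("g%03d", seq_len(n_genes)),
    rep(c("a", "b"), n_per_class)
  )
}

onemax_fitness <- function(bits) sum(bits)

all_bitstrings <- function(l) {
  as.matrix(expand.grid(rep(list(0:1), l)))[, l:1, drop = FALSE]
}

bits_index <- function(bits) sum(bits * 2^(seq_along(bits) - 1L)) + 1L
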