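test_that("normalization yields zero-mean unit-sd rows and guards constants", {
  data <- noise_dataset()
  data$matrix[5, ] <- 3.7  # constant gene
  data$matrix[6, ] <- data$matrix[6, ] * 1e4 + 100  # wild scale
  norm <- normalize_expression(data)
  expect_equal(unname(rowMeans(norm$matrix)), rep(0, 30), tolerance = 1e-9)
  sds <- apply(norm$matrix, 1, sd)
  expect_equal(unname(sds[-5]), rep(1, 29), tolerance = 1e-9)
  expect_true(all(norm$matrix[5, ] == 0))
  # idempotence
  twice <- normalize_expression(norm)
  expect_equal(twice$matrix, norm$matrix, tolerance = 1e-9)
})

test_that("t_test_rank agrees with stats::t.test gene by gene", {
  data <- noise_dataset(n_genes = 40L, n_per_class = c(6L, 9L), seed = 9L)
  for (var_equal in c(TRUE, FALSE)) {
    ranking <- t_test_rank(data, var_equal = var_equal)
    g1 <- data$labels == levels(data$labels)[1]
    for (gene in sample(data$gene_ids, 15)) {
      row <- data$matrix[gene, ]
      ref <- t.test(row[g1], row[!g1], var.equal = var_equal)
      got <- ranking[ranking$gene_id == gene, ]
      expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("ranking is sorted by ascending p with deterministic tie-breaks", {
  data <- noise_dataset(n_genes = 50L)
  data$matrix[10, ] <- data$matrix[4, ]  # exact duplicate gene: tied p
  ranking <- t_test_rank(data)
  expect_true(all(diff(ranking$p_value) >= 0))
  expect_identical(ranking$rank, seq_len(50L))
  expect_setequal(ranking$gene_id, data$gene_ids)
  dup <- match(c("g004", "g010"), ranking$gene_id)
  expect_lt(dup[1], dup[2])  # earlier original index wins the tie
})

test_that("degenerate genes rank sanely: null gene p = 1, separated gene p = 0", {
  m <- matrix(rnorm(40), 4, 10)
  m[1, ] <- rep(c(1, 2, 1, 2, 1), 2)         # identical pattern per class
  m[2, ] <- rep(c(0, 0), c(5, 5))            # constant: zero variance, no diff
  m[3, ] <- rep(c(-1, 1), c(5, 5))           # zero variance, perfect split
  data <- expression_dataset(m, paste0("g", 1:4), rep(c("a", "b"), each = 5))
  ranking <- t_test_rank(data)
  expect_equal(ranking$p_value[ranking$gene_id == "g1"], 1)
  expect_equal(ranking$t_statistic[ranking$gene_id == "g1"], 0)
  expect_equal(ranking$p_value[ranking$gene_id == "g2"], 1)
  expect_equal(ranking$p_value[ranking$gene_id == "g3"], 0)
  expect_identical(ranking$gene_id[1], "g3")
})

test_that("t statistics flip sign but keep p-values under label swap", {
  data <- noise_dataset(seed = 13L)
  r1 <- t_test_rank(data)
  swapped <- expression_dataset(
    data$matrix, data$gene_ids,
    ifelse(data$labels == "a", "b", "a")  # exchange class memberships
  )
  r2 <- t_test_rank(swapped)
  ord1 <- r1[order(r1$gene_id), ]
  ord2 <- r2[order(r2$gene_id), ]
  expect_equal(ord1$t_statistic, -ord2$t_statistic, tolerance = 1e-9)
  expect_equal(ord1$p_value, ord2$p_value, tolerance = 1e-9)
})

test_that("a strongly shifted gene ranks first across seeded generations", {
  hits <- 0L
  for (s in 1:50) {
    sim <- simulate_expression(n_per_class = c(20L, 20L), n_genes = 200L,
                               n_informative = 1L, effect_size = 3, seed = s)
    ranking <- t_test_rank(normalize_expression(sim$dataset))
    if (ranking$gene_id[1] == sim$informative_genes) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("null p-values are uniform on pure-noise data", {
  sim <- simulate_expression(n_per_class = c(10L, 10L), n_genes = 2000L,
                             n_informative = 0L, seed = 77L)
  ranking <- t_test_rank(sim$dataset)
  ks <- suppressWarnings(ks.test(ranking$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("normalization preserves the t-test ordering of the raw data", {
  data <- noise_dataset(n_genes = 100L, n_per_class = c(8L, 8L), seed = 31L)
  # give genes wildly different scales and offsets (location-scale changes)
  set.seed(32)
  data$matrix <- data$matrix * runif(100, 0.01, 100) + rnorm(100, sd = 50)
  raw <- t_test_rank(data)
  norm <- t_test_rank(normalize_expression(data))
  expect_identical(raw$gene_id, norm$gene_id)
})

test_that("select_top_k keeps the k smallest p-values in rank order", {
  data <- noise_dataset(n_genes = 60L)
  ranking <- t_test_rank(data)
  top <- select_top_k(ranking, 10L)
  expect_identical(length(top), 10L)
  brute <- ranking$gene_id[order(ranking$p_value)][1:10]
  expect_setequal(top, brute)
  expect_identical(select_top_k(ranking, 500L), ranking$gene_id)
})

test_that("t-testing requires two samples per class", {
  m <- matrix(rnorm(12), 3, 4)
  data <- expression_dataset(m, paste0("g", 1:3), c("a", "b", "b", "b"))
  expect_error(t_test_rank(data), "at least two samples")
})
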