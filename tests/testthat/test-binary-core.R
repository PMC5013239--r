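test_that("hamming counts differing positions and rejects length mismatch", {
  expect_identical(hamming("1011001010", "1011001010"), 0L)
  expect_identical(hamming("1111", "0000"), 4L)
  # position-by-position: strings differ at positions 1, 5, 6, 7, 8
  expect_identical(hamming("1011001010", "0010010110"), 5L)
  expect_error(hamming("101", "10"), "equal length")
})

test_that("hamming satisfies the metric axioms on all pairs up to length 6", {
  for (l in 1:6) {
    strings <- all_bitstrings(l)
    n <- nrow(strings)
    D <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      D[i, j] <- hamming(strings[i, ], strings[j, ])
    }
    expect_true(all(D == t(D)))                    # symmetry
    expect_true(all(diag(D) == 0L))                # identity
    expect_true(all(D[upper.tri(D)] > 0L))         # distinct strings differ
    for (k in seq_len(n)) {                        # triangle inequality
      expect_true(all(D <= outer(D[, k], D[k, ], `+`)))
    }
  }
})

test_that("get_mbest takes the per-bit strict majority of the personal bests", {
  set.seed(1)
  expect_identical(get_mbest(list("111", "111", "000")), as_bits("111"))
  expect_identical(get_mbest(list("1010")), as_bits("1010"))
  # odd count, no possible ties: deterministic and order-invariant
  pb <- list("10110", "10010", "00111", "10100", "11010")
  ref <- get_mbest(pb)
  for (r in 1:10) expect_identical(get_mbest(sample(pb)), ref)
  expect_error(get_mbest(list()), "non-empty")
})

test_that("exact per-bit ties in get_mbest resolve to 1 with probability 0.5", {
  set.seed(202)
  draws <- replicate(10000, get_mbest(list("10", "01")))
  freq1 <- rowMeans(draws)
  expect_true(all(abs(freq1 - 0.5) <= 0.02))
})

test_that("the local attractor lies between its parents", {
  set.seed(3)
  expect_identical(get_local_attractor("0110", "0110"), as_bits("0110"))
  for (mode in c("one-point", "multipoint")) {
    for (r in 1:1000) {
      p <- as.integer(runif(50) < 0.5)
      g <- as.integer(runif(50) < 0.5)
      child <- get_local_attractor(p, g, mode = mode)
      expect_true(all(child == p | child == g))
      expect_identical(hamming(child, p) + hamming(child, g), hamming(p, g))
    }
  }
  expect_error(get_local_attractor("10", "100"), "equal length")
})

test_that("one-point crossover can produce both head-from-pbest offspring", {
  # with parents 1111/0000 every offspring is a run of one parent's bits
  # followed by the other's; all 4 bits come from exactly one cut
  set.seed(4)
  kids <- replicate(200, bits_to_string(get_local_attractor("1111", "0000")))
  expect_true(all(grepl("^1*0*$|^0*1*$", kids)))
  expect_true("1100" %in% kids)  # cut after position 2, head from pbest
  expect_true("0011" %in% kids)  # same cut, other offspring
})

test_that("jump_length implements the ceiling jump and capped probability", {
  x <- as_bits("1111111111")
  m <- as_bits("0000000000")
  # hamming = 0: b = 0 and pr = 0 whatever mu is drawn
  set.seed(5)
  d0 <- jump_length(x, x)
  expect_identical(d0$b, 0L)
  expect_identical(d0$pr, 0)
  # ln(1/mu) = 1 at mu = exp(-1): b = ceiling(1 * 10 * 1) = 10
  d1 <- jump_length(x, m, ce_coefficient = 1, mu = exp(-1))
  expect_identical(d1$b, 10L)
  expect_equal(d1$pr, 1)
  # ce=1, hamming=3, mu=0.9: b = ceiling(0.3161) = 1
  d2 <- jump_length(as_bits("111"), as_bits("000"), mu = 0.9)
  expect_identical(d2$b, 1L)
  expect_equal(d2$pr, 1 / 3)
  # pr caps at 1 when b exceeds the substring length
  d3 <- jump_length(x, m, ce_coefficient = 50, mu = 0.01)
  expect_identical(d3$pr, 1)
})

test_that("jump length is zero iff the particle sits on mbest, pr monotone in b", {
  set.seed(6)
  for (r in 1:200) {
    x <- as.integer(runif(12) < 0.5)
    m <- as.integer(runif(12) < 0.5)
    d <- jump_length(x, m)
    expect_identical(d$b == 0L, hamming(x, m) == 0L)
    expect_equal(d$pr, min(d$b / 12, 1))
  }
})

test_that("mutate_toward flips bits independently with the drawn probability", {
  p <- as_bits("10110")
  expect_identical(mutate_toward(p, 0), p)
  expect_identical(mutate_toward(p, 1), as_bits("01001"))
  set.seed(7)
  l <- 50L
  p50 <- as.integer(runif(l) < 0.5)
  disp <- replicate(10000, hamming(mutate_toward(p50, 0.1), p50))
  expect_lt(abs(mean(disp) - 5), 0.3)  # binomial mean l * pr = 5
})

test_that("mutation displacement is Binomial(l, pr) distributed", {
  set.seed(8)
  l <- 50L
  pr <- 0.1
  p <- as.integer(runif(l) < 0.5)
  disp <- replicate(10000, hamming(mutate_toward(p, pr), p))
  ecdf_d <- ecdf(disp)
  ks_stat <- max(abs(ecdf_d(0:l) - pbinom(0:l, l, pr)))
  expect_lt(ks_stat, 0.02)
  chi <- suppressWarnings(
    chisq.test(tabulate(pmin(disp, 12L) + 1L, nbins = 13L),
               p = c(dbinom(0:11, l, pr), 1 - pbinom(11, l, pr)))
  )
  expect_gt(chi$p.value, 0.001)
})
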