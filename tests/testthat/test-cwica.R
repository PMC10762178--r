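test_that("two-block splits partition the channels into near-equal halves", {
  s <- split_two_blocks(20, seed = 1)
  expect_length(s$block1_rows, 10)
  expect_length(s$block2_rows, 10)
  expect_setequal(c(s$block1_rows, s$block2_rows), 1:20)
  odd <- split_two_blocks(7, seed = 1)
  expect_length(odd$block1_rows, 4)
  expect_length(odd$block2_rows, 3)
  expect_setequal(c(odd$block1_rows, odd$block2_rows), 1:7)
  expect_error(split_two_blocks(3), "at least 4")
})

test_that("splitting assigns each channel to block 1 about half the time", {
  p <- 30
  hits <- integer(p)
  for (seed in 0:99) {
    hits <- hits + (1:p %in% split_two_blocks(p, seed = seed)$block1_rows)
  }
  # two-sided binomial bounds at family-wise alpha = 0.01 over the p channels
  lo <- qbinom(0.005 / p, 100, 0.5)
  hi <- qbinom(1 - 0.005 / p, 100, 0.5)
  expect_true(all(hits >= lo & hits <= hi))
})

test_that("cross-block Spearman matrix matches a rank-then-Pearson oracle", {
  # the spec's tied five-sample pair
  expect_equal(rank_correlation_block(matrix(c(3, 1, 2, 5, 4), 1),
                                      matrix(c(2, 1, 1, 4, 5), 1))[1, 1],
               spearman_oracle(c(3, 1, 2, 5, 4), c(2, 1, 1, 4, 5)),
               tolerance = 1e-12)
  # rank invariance under a strictly increasing map
  expect_equal(rank_correlation_block(matrix(1:5, 1),
                                      matrix((1:5)^2, 1))[1, 1], 1)
  # self-correlation diagonal
  set.seed(42)
  S <- matrix(rnorm(4 * 50), 4)
  expect_equal(diag(rank_correlation_block(S, S)), rep(1, 4))
  # random vectors with heavy ties, against the oracle
  set.seed(7)
  for (k in 1:50) {
    x <- round(rnorm(23), 1)
    y <- round(rnorm(23), 1)
    expect_equal(rank_correlation_block(matrix(x, 1), matrix(y, 1))[1, 1],
                 spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate constant components correlate as zero with a warning", {
  S1 <- rbind(rep(1, 10), rnorm(10))
  S2 <- matrix(rnorm(20), 2)
  expect_warning(P <- rank_correlation_block(S1, S2), "degenerate")
  expect_equal(P[1, ], c(0, 0))
  expect_true(all(abs(P) <= 1))
})

test_that("R_q is the minimum over columns of the maximum absolute entry", {
  expect_equal(rq_statistic(diag(3)), 1)
  expect_equal(rq_statistic(matrix(0, 4, 4)), 0)
  block <- rbind(c(0.9, 0.1, 0.2), c(0.1, -0.8, 0.3), c(0.2, 0.1, 0.05))
  expect_equal(rq_statistic(block), 0.3)
})

test_that("R_q equals the exhaustive oracle and ignores sign and order", {
  set.seed(11)
  for (k in 1:200) {
    q <- sample(2:10, 1)
    P <- matrix(runif(q * q, -1, 1), q)
    expect_equal(rq_statistic(P), rq_oracle(P), tolerance = 1e-12)
    # sign flips and row/column permutations leave R_q unchanged
    sflip <- diag(sample(c(-1, 1), q, replace = TRUE))
    perm <- sample(q)
    expect_identical(rq_statistic(P), rq_statistic((sflip %*% P)[perm, ]))
  }
})

test_that("first differences subtract adjacent R values and respect gaps", {
  expect_equal(unname(first_differences(c(1, 1, 0.2))), c(0, -0.8))
  expect_equal(unname(first_differences(rep(0.7, 5))), rep(0, 4))
  d <- first_differences(c(0.97, 0.95, 0.96, 0.91, 0.30, 0.25))
  expect_equal(as.integer(names(d)[which.min(d)]), 6L)
  # a missing R kills both adjacent differences
  dna <- first_differences(c(0.9, NA, 0.8, 0.7))
  expect_true(is.na(dna[["3"]]) && is.na(dna[["4"]]))
  expect_equal(dna[["5"]], -0.1)
  expect_error(first_differences(c(0.5, NA, NA)), "at least 2")
  expect_error(first_differences(c(0.5, NA, 0.4, NA)), "consecutive")
})

test_that("the drop rule selects the dimension preceding the largest drop", {
  expect_equal(as.integer(select_q_single(c(0.97, 0.95, 0.96, 0.91, 0.30, 0.25))), 5L)
  expect_equal(as.integer(select_q_single(c(1, 0))), 2L)
  # equal drops resolve toward the smaller dimension
  expect_equal(as.integer(select_q_single(c(0.9, 0.4, 0.9, 0.4))), 2L)
  # monotone rise: fall back to the maximal R, flagged
  est <- select_q_single(c(0.2, 0.4, 0.9))
  expect_true(attr(est, "fallback"))
  expect_equal(as.integer(est), 4L)
})

test_that("cw_ica is deterministic and validates a_max", {
  fx <- make_mixture(3, 12, 256, source_seed = 8, mix_seed = 9)
  a <- cw_ica(fx$signals, a_max = 6, rep = 1, seed = 4)
  b <- cw_ica(fx$signals, a_max = 6, rep = 1, seed = 4)
  expect_identical(a$profile$r_values, b$profile$r_values)
  expect_identical(a$q_opt, b$q_opt)
  expect_error(cw_ica(fx$signals, a_max = 7), "floor\\(p/2\\)")
  expect_error(cw_ica(fx$signals, a_max = 6, rep = 0), "rep")
})

test_that("the R profile stays in [0, 1], peaks at the true dimension and
           collapses under over-decomposition", {
  fx <- make_mixture(5, 20, 500)
  res <- cw_ica(fx$signals, a_max = 10, rep = 5, seed = 3)
  r <- res$profile$r_values
  expect_true(all(r >= 0 & r <= 1, na.rm = TRUE))
  r_mean <- colMeans(r, na.rm = TRUE)
  # reproducibility is maximal at q_true and collapses two steps past it
  expect_equal(as.integer(names(which.max(r_mean))), 5L)
  expect_lt(r_mean[["7"]], r_mean[["5"]])
  expect_gt(r_mean[["5"]], 0.9)
  expect_lt(r_mean[["8"]], 0.3)
  expect_equal(res$q_opt, 5L)
})
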