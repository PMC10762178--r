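test_that("Durbin-Watson statistic matches hand arithmetic", {
  expect_equal(dw_statistic(c(1, 1, 1, 1)), 0)
  # numerator 3 * 4 = 12, denominator 4
  expect_equal(dw_statistic(c(1, -1, 1, -1)), 3)
  expect_warning(z <- dw_statistic(rep(0, 8)), "all-zero")
  expect_equal(z, 0)
  expect_error(dw_statistic(1), "at least 2")
})

test_that("Durbin-Watson statistic is bounded by [0, 4] and is near 2 for
           white noise", {
  set.seed(5)
  for (k in 1:200) {
    v <- rnorm(sample(5:60, 1)) * 10^runif(1, -3, 3)
    dw <- dw_statistic(v)
    expect_gte(dw, 0)
    expect_lte(dw, 4)
  }
  set.seed(6)
  expect_true(all(abs(replicate(5, dw_statistic(rnorm(10000))) - 2) < 0.1))
})

test_that("DW determination recovers the dimension of a noiseless mixture", {
  fx <- make_mixture(5, 20, 500)
  prof <- suppressWarnings(dw_determination(fx$signals, a_max = 10, seed = 1))
  expect_true(all(prof$dw_values >= 0 & prof$dw_values <= 4, na.rm = TRUE))
  # beyond the true dimension the reconstruction is exact: DW drops to zero
  expect_lt(prof$mean_dw[["8"]], prof$mean_dw[["3"]])
  expect_equal(prof$q_opt, 5L)
  again <- suppressWarnings(dw_determination(fx$signals, a_max = 10, seed = 1))
  expect_identical(prof$dw_values, again$dw_values)
})

test_that("a full-dimensional decomposition leaves an all-zero residual", {
  fx <- make_mixture(3, 6, 256, source_seed = 2, mix_seed = 3)
  expect_warning(prof <- dw_determination(fx$signals, a_max = 6, seed = 1),
                 "all-zero")
  expect_true(all(prof$dw_values[, "6"] == 0))
})

test_that("known-source correlation peaks once the matching component
           emerges", {
  fx <- make_mixture(5, 20, 500)
  y <- fx$sources$signals[5, ]
  prof <- ica_corr_y(fx$signals, y, a_max = 10, seed = 1)
  expect_true(all(prof$best_corr >= 0 & prof$best_corr <= 1, na.rm = TRUE))
  # from q_true on, some fit contains a component matching y almost exactly;
  # individual over-decomposed fits may dilute the match, so the per-q floor
  # is looser than the peak
  expect_gt(max(prof$best_corr[as.character(5:10)]), 0.95)
  expect_true(all(prof$best_corr[as.character(5:10)] > 0.6))
  expect_true(prof$q_opt %in% 5:10)
  # sign of the known source is irrelevant
  flipped <- ica_corr_y(fx$signals, -y, a_max = 10, seed = 1)
  expect_equal(prof$best_corr, flipped$best_corr)
})

test_that("known-source correlation stays low for an unrelated source", {
  fx <- make_mixture(5, 20, 512, source_seed = 3, mix_seed = 4)
  set.seed(99)
  y <- rnorm(512)
  prof <- ica_corr_y(fx$signals, y, a_max = 10, seed = 1)
  expect_true(all(prof$best_corr < 0.5, na.rm = TRUE))
  expect_error(ica_corr_y(fx$signals, rep(1, 512)), "constant")
})

test_that("block-count constraint arithmetic is enforced", {
  fx <- make_mixture(3, 8, 256, source_seed = 5, mix_seed = 6)
  res <- ica_by_blocks(fx$signals, n_blocks = 3, a_max = 3, seed = 1)
  expect_true(is.integer(res$q_opt))
  expect_error(ica_by_blocks(fx$signals, n_blocks = 3, a_max = 4, seed = 1),
               "ceiling")
})

test_that("two-block ICA-by-Blocks coincides with one repetition of CW_ICA", {
  fx <- make_mixture(4, 16, 400, source_seed = 7, mix_seed = 8)
  blocks <- ica_by_blocks(fx$signals, n_blocks = 2, a_max = 8,
                          correlation = "spearman", seed = 12)
  cw <- cw_ica(fx$signals, a_max = 8, rep = 1,
               correlation = "spearman", seed = 12)
  expect_identical(blocks$profile$r_values, cw$profile$r_values)
  expect_identical(blocks$q_opt, cw$q_opt)
})
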