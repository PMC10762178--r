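test_that("accuracy is the exact percentage of correct runs", {
  rep1 <- icdim:::new_accuracy_report(rep(5L, 5), rep(NA_character_, 5), 5L,
                                      list(method = "cwica", backend = "fastica"))
  expect_equal(rep1$accuracy, 100)
  est <- c(rep(8L, 20), rep(7L, 3), NA_integer_, 9L)
  rep2 <- icdim:::new_accuracy_report(est, rep(NA_character_, 25), 8L,
                                      list(method = "cwica", backend = "fastica"))
  expect_equal(rep2$correct_runs, 20L)
  expect_equal(rep2$total_runs, 25L)
  expect_equal(rep2$accuracy, 80)
  # a failed run counts as incorrect, never dropped
  expect_equal(length(rep2$per_run_estimates), 25L)
})

test_that("the accuracy harness keeps sources fixed and redraws mixings", {
  reports <- accuracy_experiment(3, p = 12, n = 256, methods = "cwica",
                                 n_runs = 2, seed = 1, rep = 3)
  rpt <- reports$cwica
  expect_s3_class(rpt, "accuracy_report")
  expect_equal(rpt$total_runs, 2L)
  expect_equal(rpt$accuracy, 100 * rpt$correct_runs / rpt$total_runs)
  expect_length(rpt$per_run_estimates, 2L)
  expect_equal(rpt$config$q_true, 3)
  # replaying the config reproduces the report exactly
  again <- accuracy_experiment(rpt$config$q_true, p = rpt$config$p,
                               n = rpt$config$n, methods = rpt$config$method,
                               n_runs = rpt$config$n_runs,
                               seed = rpt$config$seed, rep = rpt$config$rep)
  expect_identical(again$cwica$per_run_estimates, rpt$per_run_estimates)
})

test_that("a degenerate robustness sweep reduces to a single estimate", {
  sw <- robustness_sweep(q_true = 3, axis = "snr_db", levels = list(NULL),
                         methods = "cwica", backends = "fastica", seed = 2,
                         p = 12, n = 256, rep = 3)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 1L)
  expect_true(is.na(sw$level))
  expect_true(is.integer(sw$estimate))
  # the channel-count axis adapts a_max per level without error
  sw2 <- robustness_sweep(q_true = 3, axis = "n_mixed_signals",
                          levels = c(8, 12), methods = "cwica", seed = 2,
                          n = 256, rep = 2)
  expect_equal(nrow(sw2), 2L)
})

test_that("matrix round trips through delimited text bit-for-bit", {
  set.seed(3)
  x <- suppressWarnings(
    signal_matrix(matrix(rnorm(15) * 10^runif(15, -8, 8), 3, 5),
                  channel_labels = c("Fz", "Cz", "Pz")))
  path <- tempfile(fileext = ".csv")
  write_matrix(x, path, header = TRUE)
  back <- suppressWarnings(read_matrix(path, header = TRUE))
  expect_identical(back$data, unname(x$data))
  expect_identical(back$channel_labels, x$channel_labels)
  # and without header
  write_matrix(x, path)
  expect_identical(suppressWarnings(read_matrix(path))$data, unname(x$data))
})

test_that("malformed delimited input is rejected with its location", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5", "6,7,8"), path)
  expect_error(read_matrix(path), "row 2")
  writeLines(c("1,2,3", "4,x,6", "7,8,9"), path)
  expect_error(read_matrix(path), "row 2, column 2")
})
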