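# Benchmark harness: accuracy and robustness experiments over the four
# determination methods.

method_labels <- c("cwica", "dw", "blocks", "icacorry")

# Run one determination method on one dataset; returns the estimate or an
# error condition message.  Failures are reported, never silently dropped.
run_method <- function(method, X, backend, seed, a_max, rep, n_blocks,
                       correlation, y) {
  est <- tryCatch(
    switch(method,
      cwica = cw_ica(X, a_max = a_max, rep = rep, backend = backend,
                     correlation = correlation, seed = seed)$q_opt,
      dw = dw_determination(X, a_max = a_max, backend = backend,
                            seed = seed)$q_opt,
      blocks = ica_by_blocks(X, n_blocks = n_blocks, a_max = a_max,
                             backend = backend, correlation = correlation,
                             seed = seed)$q_opt,
      icacorry = ica_corr_y(X, y = y, a_max = a_max, backend = backend,
                            seed = seed)$q_opt,
      stop("unknown method '", method, "'")),
    error = function(e) structure(NA_integer_, reason = conditionMessage(e)))
  est
}

new_accuracy_report <- function(estimates, reasons, q_true, config) {
  n <- length(estimates)
  m <- sum(estimates == q_true, na.rm = TRUE)
  structure(list(correct_runs = m, total_runs = n,
                 accuracy = 100 * m / n,
                 per_run_estimates = estimates,
                 failure_reasons = reasons,
                 config = config),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report (", x$config$method, " + ", x$config$backend, "): ",
      x$correct_runs, "/", x$total_runs, " correct = ",
      round(x$accuracy, 1), "%\n", sep = "")
  cat("  estimates:", paste(x$per_run_estimates, collapse = " "), "\n")
  invisible(x)
}

#' Accuracy experiment over repeated random mixing matrices
#'
#' One fixed source set is mixed `n_runs` times with fresh random mixing
#' matrices; every requested determination method estimates the dimension of
#' each mixture and its accuracy is the percentage of runs recovering
#' `q_true`.  The known source handed to the `"icacorry"` method is the last
#' catalog source.
#'
#' @param q_true true number of sources.
#' @param p number of mixed channels.
#' @param n signal length.
#' @param methods character vector among `"cwica"`, `"dw"`, `"blocks"`,
#'   `"icacorry"`.
#' @param backend a [backend_spec()] or backend name.
#' @param n_runs number of simulation runs.
#' @param seed master seed; sources, mixings and method seeds derive from it.
#' @param snr_db optional per-channel SNR of the mixtures in dB
#'   (`NULL` = noiseless).
#' @param freq_scale frequency multiplier forwarded to [simulate_sources()].
#' @param a_max candidate-dimension ceiling (default `floor(p / 2)`).
#' @param rep CW_ICA repetitions per run.
#' @param n_blocks block count for the `"blocks"` method.
#' @param correlation correlation type for the split-half methods.
#' @return A named list of `accuracy_report` objects, one per method.
#' @examples
#' \donttest{
#' accuracy_experiment(3, p = 12, n = 256, methods = "cwica", n_runs = 2,
#'                     seed = 1, rep = 3)
#' }
#' @export
accuracy_experiment <- function(q_true, p, n, methods = "cwica",
                                backend = backend_spec("fastica"),
                                n_runs = 25L, seed = 1, snr_db = NULL,
                                freq_scale = 1, a_max = NULL, rep = 10L,
                                n_blocks = 2L,
                                correlation = c("spearman", "pearson")) {
  correlation <- match.arg(correlation)
  backend <- as_backend(backend)
  methods <- match.arg(methods, method_labels, several.ok = TRUE)
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("'n_runs' must be at least 1")
  a_max <- as.integer(a_max %||% (p %/% 2L))
  sources <- simulate_sources(q_true, n, freq_scale = freq_scale, seed = seed)
  y_known <- sources$signals[q_true, ]
  estimates <- matrix(NA_integer_, n_runs, length(methods),
                      dimnames = list(NULL, methods))
  reasons <- matrix(NA_character_, n_runs, length(methods),
                    dimnames = list(NULL, methods))
  for (r in seq_len(n_runs)) {
    mixed <- mix_signals(sources, p, snr_db = snr_db, seed = seed + 811L * r)
    for (mth in methods) {
      est <- run_method(mth, mixed$signals, backend,
                        seed = seed + 104729L * r, a_max = a_max, rep = rep,
                        n_blocks = n_blocks, correlation = correlation,
                        y = y_known)
      estimates[r, mth] <- as.integer(est)
      reasons[r, mth] <- attr(est, "reason") %||% NA_character_
    }
  }
  reports <- lapply(methods, function(mth) {
    config <- list(method = mth, backend = backend$name, q_true = q_true,
                   p = p, n = n, snr_db = snr_db, freq_scale = freq_scale,
                   a_max = a_max, rep = rep, n_blocks = n_blocks,
                   correlation = correlation, n_runs = n_runs, seed = seed)
    new_accuracy_report(estimates[, mth], reasons[, mth], q_true, config)
  })
  stats::setNames(reports, methods)
}

#' Robustness sweep over one data-generating axis
#'
#' Regenerates the study design at each level of one axis
#' (`n_mixed_signals`, `signal_length`, `snr_db` or `freq_scale`), holding
#' everything else at the defaults (`p = 30`, `n = 512`, noiseless,
#' `freq_scale = 1`), and records the estimate of every (method, backend)
#' combination at every level.
#'
#' @param q_true true number of sources (the robustness design uses 5).
#' @param axis one of `"n_mixed_signals"`, `"signal_length"`, `"snr_db"`,
#'   `"freq_scale"`.
#' @param levels vector (or list, for `snr_db` with `NULL` = noiseless
#'   entries) of axis values.
#' @param methods determination methods to run (see
#'   [accuracy_experiment()]).
#' @param backends list of [backend_spec()]s or character vector of backend
#'   names.
#' @param seed master seed.
#' @param p,n,snr_db,freq_scale defaults for the axes not being swept.
#' @param rep CW_ICA repetitions.
#' @param n_blocks block count for the `"blocks"` method.
#' @param correlation correlation type for the split-half methods.
#' @return A `sweep_result`: a long-format data frame with columns `axis`,
#'   `level`, `method`, `backend`, `estimate` (`NA` = failed, see
#'   `failure`), `failure`.
#' @export
robustness_sweep <- function(q_true = 5L, axis = c("n_mixed_signals",
                                                   "signal_length", "snr_db",
                                                   "freq_scale"),
                             levels, methods = "cwica", backends = "fastica",
                             seed = 1, p = 30L, n = 512L, snr_db = NULL,
                             freq_scale = 1, rep = 10L, n_blocks = 2L,
                             correlation = c("spearman", "pearson")) {
  axis <- match.arg(axis)
  correlation <- match.arg(correlation)
  methods <- match.arg(methods, method_labels, several.ok = TRUE)
  if (!is.list(levels)) levels <- as.list(levels)
  if (length(levels) == 0L) stop("'levels' must be nonempty")
  backends <- lapply(backends, as_backend)
  rows <- list()
  for (l in seq_along(levels)) {
    lev <- levels[[l]]
    p_l <- if (axis == "n_mixed_signals") as.integer(lev) else as.integer(p)
    n_l <- if (axis == "signal_length") as.integer(lev) else as.integer(n)
    snr_l <- if (axis == "snr_db") lev else snr_db
    fs_l <- if (axis == "freq_scale") lev else freq_scale
    sources <- simulate_sources(q_true, n_l, freq_scale = fs_l,
                                seed = seed + 13L * l)
    mixed <- mix_signals(sources, p_l, snr_db = snr_l, seed = seed + 17L * l)
    a_max <- p_l %/% 2L
    for (be in backends) {
      for (mth in methods) {
        est <- run_method(mth, mixed$signals, be, seed = seed + 19L * l,
                          a_max = a_max, rep = rep, n_blocks = n_blocks,
                          correlation = correlation,
                          y = sources$signals[q_true, ])
        rows[[length(rows) + 1L]] <- data.frame(
          axis = axis,
          level = if (is.null(lev)) NA_real_ else as.numeric(lev),
          method = mth, backend = be$name,
          estimate = as.integer(est),
          failure = attr(est, "reason") %||% NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "q_true") <- q_true
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}
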