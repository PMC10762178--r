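#' Durbin-Watson statistic of a residual signal
#'
#' Ratio of the sum of squared successive differences to the sum of squares:
#' near 0 for a smooth (signal-carrying) residual, near 2 for white noise,
#' up to 4 for a sign-alternating residual.  An all-zero residual (perfect
#' reconstruction) is defined as 0 with a warning.
#'
#' @param residual_row numeric vector of length at least 2.
#' @return A single number in `[0, 4]`.
#' @examples
#' dw_statistic(c(1, -1, 1, -1))
#' @export
dw_statistic <- function(residual_row) {
  r <- as.numeric(residual_row)
  if (length(r) < 2L) stop("need at least 2 samples")
  if (anyNA(r)) stop("residual contains missing values")
  denom <- sum(r^2)
  if (denom == 0) {
    warning("all-zero residual (perfect reconstruction); DW defined as 0")
    return(0)
  }
  sum(diff(r)^2) / denom
}

#' Durbin-Watson determination of the number of components
#'
#' For every candidate dimension `q` the full data are decomposed,
#' reconstructed, and the per-channel Durbin-Watson statistic of the
#' residual `X - X_hat` is averaged over channels.  As `q` passes the true
#' dimension the residual turns from structured signal into noise and the
#' mean DW value jumps toward 2; the automated rule selects `q* - 1` where
#' `q*` maximizes the first difference of the mean DW curve.  That rule is
#' this package's formalization of the published practice of reading the
#' jump off a heatmap, and is labelled as such in `method_flag`.
#'
#' @inheritParams cw_ica
#' @param a_max largest candidate dimension (`2 <= a_max <= p`); default
#'   `floor(p / 2)`.
#' @return An object of class `dw_profile`: `dw_values` (channels x
#'   candidates table for heatmap export), `mean_dw`, `q_opt` and
#'   `method_flag`.
#' @export
dw_determination <- function(X, a_max = NULL,
                             backend = backend_spec("fastica"), seed = 1) {
  backend <- as_backend(backend)
  m <- signal_data(X)
  p <- nrow(m)
  a_max <- as.integer(a_max %||% (p %/% 2L))
  if (a_max < 2L || a_max > p) stop("'a_max' must satisfy 2 <= a_max <= p")
  q_values <- seq.int(2L, a_max)
  dw_values <- matrix(NA_real_, p, length(q_values),
                      dimnames = list(NULL, q_values))
  for (j in seq_along(q_values)) {
    q <- q_values[j]
    fit <- tryCatch(fit_ica(m, q, backend, seed = seed + q),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    resid <- m - reconstruct(fit, m)$data
    # a residual that is pure floating-point dust is a perfect reconstruction
    tiny <- sqrt(rowSums(resid^2)) < 1e-10 * sqrt(rowSums(m^2))
    resid[tiny, ] <- 0
    dw_values[, j] <- apply(resid, 1L, dw_statistic)
  }
  mean_dw <- colMeans(dw_values)
  d <- diff(mean_dw)
  if (all(is.na(d))) stop("no consecutive successful fits: cannot locate a DW jump")
  qstar <- q_values[-1][which.max(ifelse(is.na(d), -Inf, d))]
  structure(list(dw_values = dw_values, mean_dw = mean_dw,
                 q_opt = qstar - 1L,
                 method_flag = "automated: argmax of first difference of mean DW",
                 backend = backend$name, seed = seed),
            class = "dw_profile")
}

#' @export
print.dw_profile <- function(x, ...) {
  cat("dw_profile (", x$backend, "): q_opt = ", x$q_opt, "\n", sep = "")
  cat("  rule:", x$method_flag, "\n")
  cat("  mean DW by q:\n")
  print(round(x$mean_dw, 3))
  invisible(x)
}

#' Known-source correlation determination (ICA_corr_y)
#'
#' Requires one source signal `y` to be known.  For every candidate
#' dimension the maximum absolute correlation between any estimated
#' component and `y` is recorded; the dimension whose model contains the
#' best-matching component is selected (smallest such `q` on ties, for
#' parsimony).
#'
#' @inheritParams cw_ica
#' @param y numeric vector of length `ncol(X)` with nonzero variance.
#' @param a_max largest candidate dimension (`2 <= a_max <= p`); default
#'   `floor(p / 2)`.
#' @param correlation `"pearson"` (default) or `"spearman"`.
#' @return An object of class `corr_y_profile` with `best_corr` (per-`q`
#'   maximum absolute correlation) and `q_opt`.
#' @export
ica_corr_y <- function(X, y, a_max = NULL,
                       backend = backend_spec("fastica"),
                       correlation = c("pearson", "spearman"), seed = 1) {
  correlation <- match.arg(correlation)
  backend <- as_backend(backend)
  m <- signal_data(X)
  p <- nrow(m)
  y <- as.numeric(y)
  if (length(y) != ncol(m)) stop("'y' must have length ncol(X) = ", ncol(m))
  if (stats::sd(y) == 0) stop("'y' is constant: no correlation is defined")
  a_max <- as.integer(a_max %||% (p %/% 2L))
  if (a_max < 2L || a_max > p) stop("'a_max' must satisfy 2 <= a_max <= p")
  q_values <- seq.int(2L, a_max)
  best_corr <- stats::setNames(rep(NA_real_, length(q_values)), q_values)
  for (j in seq_along(q_values)) {
    fit <- tryCatch(fit_ica(m, q_values[j], backend, seed = seed + q_values[j]),
                    error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    best_corr[j] <- max(abs(stats::cor(t(fit$components), y,
                                       method = correlation)))
  }
  if (all(is.na(best_corr))) stop("every ICA fit failed")
  q_opt <- q_values[which.max(ifelse(is.na(best_corr), -Inf, best_corr))]
  structure(list(best_corr = best_corr, q_opt = as.integer(q_opt),
                 correlation = correlation, backend = backend$name,
                 seed = seed),
            class = "corr_y_profile")
}

#' @export
print.corr_y_profile <- function(x, ...) {
  cat("corr_y_profile (", x$backend, ", ", x$correlation, "): q_opt = ",
      x$q_opt, "\n", sep = "")
  print(round(x$best_corr, 3))
  invisible(x)
}

#' ICA-by-Blocks determination of the number of components
#'
#' The channels are split once into `n_blocks` random near-equal blocks and
#' each block is decomposed at every candidate dimension.  Each `q` is
#' scored by the minimum over block pairs of the split-half statistic
#' ([rq_statistic()]); the dimension preceding the largest drop of that
#' score is selected.  The drop rule replaces the published practice of
#' reading the drop off a signal-correlation plot, and the single split (no
#' repetitions) follows the original method.  With `n_blocks = 2` and the
#' same seed this reproduces exactly one repetition of [cw_ica()].
#'
#' @inheritParams cw_ica
#' @param n_blocks number of blocks (at least 2).
#' @param a_max largest candidate dimension; must not exceed
#'   `ceiling(p / n_blocks)` (the largest block must support it; dimensions
#'   exceeding a smaller block are scored from the remaining block pairs).
#'   Default `floor(p / n_blocks)`.
#' @param correlation `"spearman"` or `"pearson"`.
#' @return A `determination_result` (see [cw_ica()]) with
#'   `method = "ica_by_blocks"` and a single-row profile.
#' @export
ica_by_blocks <- function(X, n_blocks = 2L, a_max = NULL,
                          backend = backend_spec("fastica"),
                          correlation = c("spearman", "pearson"), seed = 1) {
  correlation <- match.arg(correlation)
  backend <- as_backend(backend)
  m <- signal_data(X)
  p <- nrow(m)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("'n_blocks' must be at least 2")
  a_max <- as.integer(a_max %||% (p %/% n_blocks))
  if (a_max < 3L) stop("'a_max' must be at least 3 to allow drop detection")
  if (a_max > ceiling(p / n_blocks)) {
    stop("'a_max' = ", a_max, " violates the block constraint ",
         "a_max <= ceiling(p / n_blocks) = ", ceiling(p / n_blocks))
  }
  blocks <- split_blocks(p, n_blocks, seed = seed + 101L)
  q_values <- seq.int(2L, a_max)
  scores <- block_scores(m, blocks, q_values, backend, correlation,
                         seed_base = seed + 1000L)
  est <- select_q_single(scores, q_values)
  profile <- structure(list(r_values = matrix(scores, 1L,
                                              dimnames = list(NULL, q_values)),
                            a_max = a_max, rep = 1L,
                            correlation = correlation, backend = backend$name),
                       class = "correlation_profile")
  structure(list(method = "ica_by_blocks", q_opt = as.integer(est),
                 per_rep_q = as.integer(est),
                 vote_counts = stats::setNames(1L, est),
                 tie_broken = FALSE, fallback = attr(est, "fallback"),
                 profile = profile, n_blocks = n_blocks,
                 backend = backend$name, correlation = correlation,
                 seed = seed),
            class = "determination_result")
}
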