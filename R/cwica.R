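#' Random partition of channels into near-equal blocks
#'
#' Channels are permuted uniformly at random and dealt into `n_blocks`
#' blocks whose sizes differ by at most one; for two blocks and odd `p` the
#' sizes are `(p+1)/2` and `(p-1)/2`.
#'
#' @param p number of channels.
#' @param n_blocks number of blocks.
#' @param seed integer seed.
#' @return A list of integer index vectors partitioning `1:p`.
#' @export
split_blocks <- function(p, n_blocks = 2L, seed = 1) {
  p <- as.integer(p)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("'n_blocks' must be at least 2")
  if (p < 2L * n_blocks) stop("p = ", p, " is too small for ", n_blocks, " blocks")
  idx <- with_seed(seed, sample.int(p))
  sizes <- rep(p %/% n_blocks, n_blocks)
  extra <- p %% n_blocks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_blocks), function(b) sort(idx[starts[b]:ends[b]]))
}

#' Split channels into two blocks for split-half determination
#'
#' @param p number of channels (at least 4).
#' @param seed integer seed.
#' @return An object of class `block_split` with `block1_rows`,
#'   `block2_rows` and `seed`.
#' @examples
#' split_two_blocks(7, seed = 1)
#' @export
split_two_blocks <- function(p, seed = 1) {
  p <- as.integer(p)
  if (p < 4L) stop("'p' must be at least 4 to run ICA on both blocks")
  blocks <- split_blocks(p, 2L, seed)
  structure(list(block1_rows = blocks[[1]], block2_rows = blocks[[2]],
                 seed = seed),
            class = "block_split")
}

#' Cross-block rank correlation matrix
#'
#' Entry `(j, k)` is the correlation between component `j` of the first
#' block and component `k` of the second block.  With
#' `method = "spearman"` values are ranked first (average ranks on ties) and
#' the product-moment correlation of the ranks is returned.  A constant
#' (zero-variance) component row correlates as 0 with a warning, the
#' conservative treatment of a degenerate component.
#'
#' @param S1,S2 `q x n` component matrices (rows are components).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `q x q` numeric matrix with entries in `[-1, 1]`.
#' @export
rank_correlation_block <- function(S1, S2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  S1 <- as.matrix(S1)
  S2 <- as.matrix(S2)
  if (!all(dim(S1) == dim(S2))) stop("'S1' and 'S2' must have the same shape")
  if (ncol(S1) < 3L) stop("components must have at least 3 samples")
  const1 <- apply(S1, 1L, function(r) stats::sd(r) == 0)
  const2 <- apply(S2, 1L, function(r) stats::sd(r) == 0)
  if (any(const1) || any(const2)) {
    warning("degenerate constant component(s); their correlations are set to 0")
  }
  P <- suppressWarnings(stats::cor(t(S1), t(S2), method = method))
  P[const1, ] <- 0
  P[, const2] <- 0
  P
}

#' Split-half reproducibility statistic R_q
#'
#' For each column of the cross-block correlation matrix, take the maximum
#' absolute entry (the best partner of that second-block component among the
#' first-block components); return the minimum of those column maxima.  A
#' value near 1 means every component of one block is reproduced in the
#' other; a value near 0 flags at least one unmatched (noise) component.
#'
#' @param block a `q x q` cross-block correlation matrix
#'   ([rank_correlation_block()] output).
#' @return A single number in `[0, 1]`.
#' @examples
#' rq_statistic(diag(3))
#' @export
rq_statistic <- function(block) {
  block <- as.matrix(block)
  min(apply(abs(block), 2L, max))
}

#' First-order differences of a reproducibility profile
#'
#' `D_q = R_q - R_{q-1}` for `q = 3, ..., A_max`.  A missing `R` value makes
#' both adjacent differences missing (no difference is taken across a gap).
#'
#' @param r_row numeric vector of `R` values for `q = q_values[1], ...`;
#'   `NA` marks a failed fit.
#' @param q_values the candidate dimensions the values correspond to
#'   (default `2, 3, ...`).
#' @return Named numeric vector of differences, names are the `q` of each
#'   difference.
#' @examples
#' first_differences(c(1, 1, 0.2))
#' @export
first_differences <- function(r_row, q_values = seq(2, length.out = length(r_row))) {
  r_row <- as.numeric(r_row)
  if (length(r_row) != length(q_values)) stop("'q_values' must match 'r_row'")
  if (sum(!is.na(r_row)) < 2L) {
    stop("need at least 2 present R values to form a difference")
  }
  d <- diff(r_row)
  names(d) <- q_values[-1]
  if (all(is.na(d))) {
    stop("no two consecutive present R values: cannot detect a drop")
  }
  d
}

#' Select the component count from one reproducibility profile
#'
#' Locates the most negative first difference `D_{q*}` (ties broken toward
#' the smallest `q*`): the collapse of reproducibility happens *at* `q*`, so
#' the selected dimension is `q* - 1`, the last value before the drop.  If
#' no difference is negative (no drop: a pathological, monotonically rising
#' profile) the `q` maximizing `R` is returned and the result carries
#' `attr(, "fallback") = TRUE`.
#'
#' @inheritParams first_differences
#' @return Integer estimate of the number of components, with attribute
#'   `fallback`.
#' @examples
#' select_q_single(c(0.97, 0.95, 0.96, 0.91, 0.30, 0.25))
#' @export
select_q_single <- function(r_row, q_values = seq(2, length.out = length(r_row))) {
  d <- first_differences(r_row, q_values)
  dq <- as.integer(names(d))
  if (any(d < 0, na.rm = TRUE)) {
    i <- which.min(ifelse(is.na(d), Inf, d)) # first minimum = smallest q*
    q <- dq[i] - 1L
    fallback <- FALSE
  } else {
    q <- as.integer(q_values[which.max(ifelse(is.na(r_row), -Inf, r_row))])
    fallback <- TRUE
  }
  structure(q, fallback = fallback)
}

# Fit every block at dimension q and score q by the minimum over block
# pairs of the split-half statistic.  Shared by cw_ica (two blocks, many
# repetitions) and ica_by_blocks (B blocks, single split): with two blocks
# and the same seeds the two are identical by construction.
block_scores <- function(X, blocks, q_values, backend, correlation, seed_base) {
  m <- signal_data(X)
  vapply(q_values, function(q) {
    comps <- lapply(seq_along(blocks), function(b) {
      rows <- blocks[[b]]
      if (q > length(rows)) return(NULL)
      fit <- tryCatch(
        fit_ica(m[rows, , drop = FALSE], q, backend,
                seed = seed_base + 500L * (b - 1L) + q),
        error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) NULL else fit$components
    })
    pair_scores <- c()
    nb <- length(blocks)
    for (b1 in seq_len(nb - 1L)) {
      for (b2 in (b1 + 1L):nb) {
        if (is.null(comps[[b1]]) || is.null(comps[[b2]])) next
        P <- rank_correlation_block(comps[[b1]], comps[[b2]], correlation)
        pair_scores <- c(pair_scores, rq_statistic(P))
      }
    }
    if (length(pair_scores) == 0L) NA_real_ else min(pair_scores)
  }, numeric(1))
}

#' CW_ICA: split-half determination of the number of independent components
#'
#' Repeatedly splits the channels into two random half-blocks, decomposes
#' each block at every candidate dimension `q = 2, ..., a_max`, and scores
#' each `q` by the smallest column-wise maximum absolute cross-block
#' correlation `R_q` ([rq_statistic()]).  Each repetition votes for the `q`
#' preceding the largest drop of its `R` profile ([select_q_single()]); the
#' modal vote across repetitions is reported, ties broken toward the
#' smallest `q`.
#'
#' @param X a [signal_matrix()] or numeric matrix, channels in rows.
#' @param a_max largest candidate dimension; must satisfy
#'   `3 <= a_max <= floor(p / 2)`.  Default `floor(p / 2)`.
#' @param rep number of random-split repetitions.
#' @param backend a [backend_spec()] or backend name.
#' @param correlation `"spearman"` (recommended) or `"pearson"`.
#' @param seed integer seed; all splits and fits derive from it.
#' @return An object of class `determination_result`: `q_opt`, `per_rep_q`
#'   (one vote per repetition, `NA` where every fit of a repetition failed),
#'   `vote_counts`, `tie_broken`, `fallback` (per-repetition flag for
#'   profiles without any drop), and `profile`, a `correlation_profile`
#'   whose `r_values` matrix (repetitions in rows, `q` in columns) is the
#'   data behind a signal-correlation plot.
#' @examples
#' \donttest{
#' s <- simulate_sources(3, 256, seed = 1)
#' m <- mix_signals(s, p = 12, seed = 2)
#' cw_ica(m$signals, a_max = 6, rep = 3, seed = 3)
#' }
#' @export
cw_ica <- function(X, a_max = NULL, rep = 10L,
                   backend = backend_spec("fastica"),
                   correlation = c("spearman", "pearson"), seed = 1) {
  correlation <- match.arg(correlation)
  backend <- as_backend(backend)
  m <- signal_data(X)
  p <- nrow(m)
  a_max <- as.integer(a_max %||% (p %/% 2L))
  rep <- as.integer(rep)
  if (rep < 1L) stop("'rep' must be at least 1")
  if (a_max < 3L) stop("'a_max' must be at least 3 to allow drop detection")
  if (a_max > p %/% 2L) {
    stop("'a_max' = ", a_max, " violates the split-half constraint ",
         "a_max <= floor(p/2) = ", p %/% 2L,
         " (each half-block must support a_max components)")
  }
  q_values <- seq.int(2L, a_max)
  r_values <- matrix(NA_real_, rep, length(q_values),
                     dimnames = list(NULL, q_values))
  per_rep_q <- rep(NA_integer_, rep)
  fallback <- rep(NA, rep)
  for (i in seq_len(rep)) {
    split <- split_two_blocks(p, seed = seed + 101L * i)
    r_values[i, ] <- block_scores(m, list(split$block1_rows, split$block2_rows),
                                  q_values, backend, correlation,
                                  seed_base = seed + 1000L * i)
    est <- tryCatch(select_q_single(r_values[i, ], q_values),
                    error = function(e) NULL)
    if (!is.null(est)) {
      per_rep_q[i] <- as.integer(est)
      fallback[i] <- attr(est, "fallback")
    }
  }
  if (all(is.na(per_rep_q))) {
    stop("every repetition failed: no usable ICA fits at any dimension")
  }
  vote <- modal_vote(per_rep_q)
  profile <- structure(list(r_values = r_values, a_max = a_max, rep = rep,
                            correlation = correlation, backend = backend$name),
                       class = "correlation_profile")
  structure(list(method = "cwica", q_opt = vote$q, per_rep_q = per_rep_q,
                 vote_counts = vote$counts, tie_broken = vote$tie_broken,
                 fallback = fallback, profile = profile,
                 backend = backend$name, correlation = correlation,
                 seed = seed),
            class = "determination_result")
}

#' @export
print.determination_result <- function(x, ...) {
  cat("Determination of the number of independent components (",
      x$method, " + ", x$backend, ")\n", sep = "")
  cat("  q_opt =", x$q_opt,
      if (isTRUE(x$tie_broken)) "(modal tie broken toward smallest q)\n" else "\n")
  if (!is.null(x$per_rep_q) && length(x$per_rep_q) > 1L) {
    cat("  votes:", paste(x$per_rep_q, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("correlation_profile: R_q for q = 2..", x$a_max, " over ", x$rep,
      " repetition(s) [", x$correlation, "]\n", sep = "")
  print(round(x$r_values, 3))
  invisible(x)
}
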