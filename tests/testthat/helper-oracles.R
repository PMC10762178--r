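# Independent oracles used to cross-check the package's statistics, plus
# small fixture builders.  Oracles are deliberately written from first
# principles so they share no code path with the implementation.

# Average ranks (ties share the mean of the ranks they occupy), written as an
# explicit double loop over values.
average_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Product-moment correlation by the direct sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

spearman_oracle <- function(x, y) pearson_oracle(average_ranks(x), average_ranks(y))

# Exhaustive min-over-columns-of-max-abs with explicit loops.
rq_oracle <- function(P) {
  q <- ncol(P)
  col_max <- numeric(q)
  for (j in seq_len(q)) {
    best <- 0
    for (i in seq_len(nrow(P))) {
      if (abs(P[i, j]) > best) best <- abs(P[i, j])
    }
    col_max[j] <- best
  }
  m <- col_max[1]
  for (j in seq_len(q)) if (col_max[j] < m) m <- col_max[j]
  m
}

# For each true source, the best absolute correlation with any estimated
# component (greedy matching oracle for recovery checks).
best_match_corr <- function(estimated, truth) {
  apply(abs(cor(t(truth), t(estimated))), 1L, max)
}

# Standard noiseless fixture: q_true catalog sources mixed to p channels.
make_mixture <- function(q_true, p, n, source_seed = 11, mix_seed = 22,
                         snr_db = NULL) {
  sources <- simulate_sources(q_true, n, seed = source_seed)
  mixed <- mix_signals(sources, p, snr_db = snr_db, seed = mix_seed)
  list(sources = sources, signals = mixed$signals, mixing = mixed$mixing)
}
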