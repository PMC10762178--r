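# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Modal vote with ties broken toward the smallest value.
modal_vote <- function(v) {
  v <- v[!is.na(v)]
  stopifnot(length(v) > 0L)
  counts <- table(v)
  winners <- as.integer(names(counts)[counts == max(counts)])
  list(q = min(winners), tie_broken = length(winners) > 1L,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
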