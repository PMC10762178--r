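#' Catalog of EEG-like source waveforms
#'
#' Eight analog waveforms mixing periodic and non-periodic character, in the
#' spirit of the component types seen in scalp EEG: narrow-band rhythms,
#' a frequency sweep, sparse transients, slow eye-blink-like bumps, and two
#' noise processes.  Frequencies are expressed in cycles per generated
#' window and are multiplied by `freq_scale` in [simulate_sources()].
#'
#' Entries 1-4 are deterministic functions of time and do not consume random
#' numbers; entries 5-8 are stochastic and depend on the generator seed.
#'
#' @return A named list of catalog entries.  Each entry is a list with
#'   elements `name`, `periodic` (logical), `stochastic` (logical) and `fun`,
#'   a function of `(n, freq_scale)` returning a length-`n` numeric vector.
#' @examples
#' names(waveform_catalog())
#' @export
waveform_catalog <- function() {
  tt <- function(n) (seq_len(n) - 1) / n
  list(
    alpha_sine = list(
      name = "alpha_sine", periodic = TRUE, stochastic = FALSE,
      fun = function(n, freq_scale) sin(2 * pi * 10 * freq_scale * tt(n))),
    theta_sawtooth = list(
      name = "theta_sawtooth", periodic = TRUE, stochastic = FALSE,
      fun = function(n, freq_scale) 2 * ((6 * freq_scale * tt(n)) %% 1) - 1),
    beta_square = list(
      name = "beta_square", periodic = TRUE, stochastic = FALSE,
      # phase nudge keeps sin() away from exact zeros so sign() never emits 0
      fun = function(n, freq_scale) sign(sin(2 * pi * 21 * freq_scale * tt(n) + 1e-9))),
    chirp = list(
      name = "chirp", periodic = TRUE, stochastic = FALSE,
      # linear sweep from 2 to 30 cycles per window
      fun = function(n, freq_scale) {
        t <- tt(n)
        sin(2 * pi * freq_scale * (2 * t + 14 * t^2))
      }),
    spike_train = list(
      name = "spike_train", periodic = FALSE, stochastic = TRUE,
      fun = function(n, freq_scale) {
        x <- numeric(n)
        k <- max(6L, round(n / 40))
        idx <- sample.int(n, k)
        x[idx] <- sample(c(-1, 1), k, replace = TRUE) * (2 + stats::rexp(k))
        x
      }),
    blink_bumps = list(
      name = "blink_bumps", periodic = FALSE, stochastic = TRUE,
      fun = function(n, freq_scale) {
        x <- numeric(n)
        w <- max(8L, round(n / 16))
        half <- w %/% 2L
        centers <- sample(seq(half + 1L, n - half), max(3L, round(n / 128)))
        for (c0 in centers) {
          i <- (c0 - half):(c0 + half)
          x[i] <- x[i] + 0.5 * (1 + cos(2 * pi * seq(-0.5, 0.5, length.out = length(i))))
        }
        x
      }),
    smoothed_noise = list(
      name = "smoothed_noise", periodic = FALSE, stochastic = TRUE,
      fun = function(n, freq_scale) {
        w <- max(4L, round(n / 64))
        as.numeric(stats::filter(stats::rnorm(n), rep(1 / w, w),
                                 sides = 2, circular = TRUE))
      }),
    laplace_noise = list(
      name = "laplace_noise", periodic = FALSE, stochastic = TRUE,
      fun = function(n, freq_scale) {
        stats::rexp(n) * sample(c(-1, 1), n, replace = TRUE)
      })
  )
}

#' Simulate EEG-like source signals
#'
#' Draws the first `q_true` waveforms from `catalog` in fixed order and
#' standardizes each to zero mean and unit (sample) variance.  Deterministic
#' waveforms are identical for every seed; stochastic waveforms are
#' reproducible functions of `seed`.
#'
#' @param q_true number of source signals (at least 2, at most the catalog
#'   size).
#' @param n signal length in samples (at least 64).
#' @param catalog a waveform catalog as returned by [waveform_catalog()].
#' @param freq_scale positive multiplier applied to all periodic-waveform
#'   frequencies; the lever behind the frequency-range robustness axis.
#' @param seed integer RNG seed.
#' @return An object of class `source_set`: list with `signals`
#'   (`q_true x n` matrix), `kinds` (waveform labels), `sample_count`,
#'   `source_count` and `seed`.
#' @examples
#' s <- simulate_sources(5, 512, seed = 1)
#' rowMeans(s$signals)
#' @export
simulate_sources <- function(q_true, n, catalog = waveform_catalog(),
                             freq_scale = 1, seed = 1) {
  q_true <- as.integer(q_true)
  n <- as.integer(n)
  if (q_true < 2L) stop("'q_true' must be at least 2")
  if (q_true > length(catalog)) {
    stop("'q_true' = ", q_true, " exceeds the catalog size (",
         length(catalog), " waveforms)")
  }
  if (n < 64L) stop("'n' must be at least 64 samples, got ", n)
  if (!is.numeric(freq_scale) || freq_scale <= 0) {
    stop("'freq_scale' must be a positive number")
  }
  entries <- catalog[seq_len(q_true)]
  signals <- with_seed(seed, {
    rows <- lapply(entries, function(e) {
      x <- e$fun(n, freq_scale)
      s <- stats::sd(x)
      if (s == 0) stop("waveform '", e$name, "' produced a constant signal")
      (x - mean(x)) / s
    })
    do.call(rbind, rows)
  })
  kinds <- unname(vapply(entries, `[[`, "", "name"))
  rownames(signals) <- kinds
  structure(list(signals = signals,
                 kinds = kinds,
                 sample_count = n, source_count = q_true, seed = seed),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat("source_set:", x$source_count, "sources x", x$sample_count, "samples\n")
  cat("kinds:", paste(x$kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Mix source signals into observed channels
#'
#' Forms `X = A S` with a `p x q_true` mixing matrix of standard-normal
#' entries (redrawn wholesale if numerically rank deficient), optionally
#' adding i.i.d. Gaussian noise to each mixed channel so that the per-channel
#' signal-to-noise ratio equals `snr_db` decibels.
#'
#' @param sources a [simulate_sources()] result (or any `source_set`).
#' @param p number of mixed channels; must be at least `sources$source_count`,
#'   and at least twice that for reliable split-half determination.
#' @param snr_db per-channel signal-to-noise ratio in dB, or `NULL` for a
#'   noiseless mixture.
#' @param seed integer RNG seed (mixing matrix, then noise).
#' @return A list with `signals` (a [signal_matrix()]) and `mixing` (class
#'   `mixing_spec`: the mixing matrix, `snr_db`, `p`, `seed`, plus the clean
#'   mixture and the realized noise for SNR auditing).
#' @examples
#' s <- simulate_sources(3, 256, seed = 1)
#' m <- mix_signals(s, p = 8, seed = 2)
#' dim(m$signals$data)
#' @export
mix_signals <- function(sources, p, snr_db = NULL, seed = 1) {
  if (!inherits(sources, "source_set")) stop("'sources' must be a source_set")
  p <- as.integer(p)
  q <- sources$source_count
  n <- sources$sample_count
  if (p < q) {
    stop("p = ", p, " mixed channels cannot carry q_true = ", q,
         " sources: the underdetermined regime (p < q) is not supported")
  }
  out <- with_seed(seed, {
    A <- matrix(stats::rnorm(p * q), p, q)
    # redraw on numerical rank deficiency
    for (tries in 1:100) {
      sv <- svd(A, nu = 0, nv = 0)$d
      if (sv[q] > 0 && sv[1] / sv[q] < 1e8) break
      A <- matrix(stats::rnorm(p * q), p, q)
    }
    clean <- A %*% sources$signals
    noise <- NULL
    X <- clean
    if (!is.null(snr_db)) {
      row_power <- rowMeans(clean^2)
      noise_sd <- sqrt(row_power / 10^(snr_db / 10))
      noise <- matrix(stats::rnorm(p * n), p, n) * noise_sd
      X <- clean + noise
    }
    list(A = A, clean = clean, noise = noise, X = X)
  })
  mixing <- structure(list(mixing_matrix = out$A, snr_db = snr_db, p = p,
                           seed = seed, clean = out$clean, noise = out$noise),
                      class = "mixing_spec")
  list(signals = signal_matrix(out$X), mixing = mixing)
}
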