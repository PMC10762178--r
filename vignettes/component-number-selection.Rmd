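---
title: "Selecting the number of independent components by split-half reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of independent components by split-half reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdim)
```

## The problem

The noiseless ICA model writes the observed channels as a linear mixture of
independent, non-Gaussian sources,

$$X_{p \times n} = A_{p \times q}\, S_{q \times n},$$

with $p$ channels of length $n$, a full-column-rank mixing matrix $A$, and
$q$ source signals.  Fitting ICA requires choosing $q$ in advance, and both
directions of error are harmful: with $q$ too small, distinct sources stay
merged in single components; with $q$ too large, genuine sources are split
and the surplus components absorb noise.  In scalp-EEG artifact removal —
the motivating application — a wrong $q$ either leaves blinks and muscle
activity inside the "clean" signal or fragments the brain signal itself.

## The split-half criterion

The estimator implemented in `cw_ica()` rests on one observation:
components that reflect true sources are *reproducible*.  If the channels
are split into two disjoint half-blocks, each half still observes the same
underlying sources, so an ICA of either half should find them.  Components
that exist only as noise in one half have no counterpart in the other.

For each candidate dimension $q$ the two half-blocks are decomposed
separately and the $q \times q$ cross-block correlation matrix
$P'$ is formed, using Spearman rank correlation by default: rank
correlation captures any monotone relationship between components, is
indifferent to the arbitrary sign and scale of ICA output, and is robust to
the heavy-tailed amplitude distributions typical of electrophysiological
sources.  Each second-block component is matched to its best first-block
partner by the column-wise maximum of $|P'|$, written $\rho_i$, and the
candidate is scored by the worst match:

$$R_q = \min_{1 \le i \le q} \max \left\{ |\rho_i| \right\}.$$

While $q$ does not exceed the true dimension, every extracted component is
reproducible and $R_q$ stays high; the first surplus component is noise,
unmatched across blocks, and $R_q$ collapses.  The collapse is located by
the first-order differences $D_q = R_q - R_{q-1}$ for $q = 3,\dots,A_{max}$:
the estimate of one repetition is $q^* - 1$ where $q^*$ minimizes $D_q$
(the collapse happens *at* $q^*$, so the last reliable dimension is one
less).  The whole procedure — random split, profile, drop detection — is
repeated `rep` times and the modal estimate wins, which protects against an
occasional unlucky split.

`ica_by_blocks()` implements the ancestor of this idea: a single split into
$B$ blocks, scored per candidate by the minimum over block pairs of the same
statistic.  With $B = 2$ it coincides exactly with one repetition of
`cw_ica()` (a regression test holds the two profiles identical); what
`cw_ica()` adds is the quantitative drop rule and the repetition/vote
layer.

## Tunable parameters

* `a_max` — the candidate-dimension ceiling, default $\lfloor p/2 \rfloor$.
  Each half-block of $\lceil p/2 \rceil$ channels must itself support
  `a_max` components, which is why the method requires
  $q \le p/2$: detecting $q$ sources needs at least $2q$ channels.
  Detectable estimates lie in $\{2, \dots, A_{max}-1\}$.
* `rep` — number of random-split repetitions, default 10.  The modal vote
  stabilizes quickly; larger values buy little beyond ~10 on the designs
  shipped here.
* `correlation` — `"spearman"` (default) or `"pearson"`.  Both work on
  clean data; rank correlation is the robust choice and the recommended
  default.
* `backend` — `"fastica"` (default), `"infomax"` or `"jade"`, with
  `max_iter` (500), `tol` (1e-6) and `retries` (3) in `backend_spec()`.
  Defaults follow common practice for these algorithms and are exposed
  because no single setting suits every dataset.

## Numerical design choices

**Whitening.**  Every fit centers the channels and projects onto exactly
`q` leading principal directions, then rescales each projected row to unit
sample variance before the backend runs.  The rescaling matters in the
over-decomposition regime: on (numerically) rank-deficient data the
directions beyond the true rank carry only floating-point residue, and
rescaling them to unit variance hands the backend a full-rank input whose
surplus dimensions are amplified numerical noise.  Those surplus components
are exactly the irreproducible ones the split-half statistic needs to see;
dividing by near-zero eigenvalues (classical whitening) or truncating to
the numerical rank would either blow up or silently cap the sweep at the
true dimension and hide the drop.  A projected row with *exactly* zero
variance cannot be rescaled; such a fit is reported as non-converged and
its profile entry left missing.

**Initialization and retries.**  FastICA and Infomax start from a random
orthogonal rotation derived from the seed; a non-converged fit is retried
up to `retries` times on sub-seeds `seed + 1000*attempt`.  JADE is a
deterministic joint diagonalization: it takes no random restart, and its
start-rotation argument survives into the output, so the engine always
initializes it with the identity.

**Missing values.**  A failed fit leaves its $R_q$ missing; a difference
$D_q$ is only formed between adjacently present values (no differencing
across gaps, which could fabricate a drop).  A repetition with fewer than
two consecutive present values casts no vote.

**Ties and pathologies.**  Equal minimal drops resolve toward the smaller
$q^*$, and modal-vote ties toward the smaller $q$ — parsimony, and a
deterministic answer.  A profile with no negative difference (no drop at
all) falls back to the $q$ maximizing $R_q$ and is flagged via the
`fallback` field.  Constant (zero-variance) components correlate as 0 with
a warning, biasing $R_q$ downward — the safe direction for drop detection.

## The simulator

`simulate_sources()` emulates the statistical structure of EEG components
rather than their physiology: a catalog of eight waveforms mixing periodic
entries (10-cycle sinusoid, 6-cycle sawtooth, 21-cycle square wave, a
2-to-30-cycle linear chirp — frequencies in cycles per window, all scaled
by `freq_scale`) with non-periodic ones (a sparse spike train, eye-blink-like
raised-cosine bumps, low-pass-filtered Gaussian noise, heavy-tailed Laplace
noise).  Every source is standardized to zero mean and unit variance; at
the default lengths all pairs are weakly dependent (absolute correlation
below 0.3).  `mix_signals()` applies a standard-normal mixing matrix
(redrawn wholesale if its condition number exceeds 1e8) and can add
per-channel Gaussian noise at a requested SNR in dB; noise is added to the
mixtures, the conventional reading for sensor-level noise.

What the simulator does *not* model: volume conduction through a head
model, electrode geometry, 1/f background spectra, non-stationarity, or
physiologically calibrated amplitudes.  Passing the recovery experiments
here therefore demonstrates that the estimator detects the dimension of a
linear, stationary, non-Gaussian mixture — the regime ICA itself assumes —
not that any particular EEG recording has a given number of sources.

One consequence of standardization is worth stating plainly.  Because all
simulated sources have equal power and the mixing is isotropic Gaussian,
the two half-blocks' leading principal subspaces differ when $q$ is below
the true dimension, so the under-decomposed components agree only partially
across blocks ($R_q$ around 0.4–0.7 rather than near 1).  The profile shape
that matters for detection — $R_q$ maximal at the true dimension and
collapsing immediately past it — is unaffected, and is what the property
tests assert.  On data with a dominant-source hierarchy (real EEG has one),
the under-decomposed regime sits higher.

## Comparators

* `dw_determination()` scores each candidate by the mean per-channel
  Durbin–Watson statistic of the reconstruction residual,
  $DW = \sum_t (r_t - r_{t-1})^2 / \sum_t r_t^2$: near 0 while the residual
  still contains structured signal, near 2 once it is white noise.  The
  published practice reads the jump off a heatmap; the automated surrogate
  used here ($q^* - 1$ at the largest first difference of the mean DW
  curve) is labelled as such in the result's `method_flag`.  Residuals that
  are pure floating-point dust (relative norm below 1e-10) are treated as
  exact reconstructions.
* `ica_corr_y()` requires one known source `y` and selects the smallest
  dimension whose model contains the component best correlated with `y` —
  simple, but the known-source requirement rarely holds in practice.
* `ica_by_blocks()` as above; its block constraint is
  `a_max <= ceiling(p / n_blocks)` and candidates exceeding a smaller
  block are scored from the remaining block pairs.

## Experiment scales

The shipped experiments run at the design sizes used throughout the
package's tests: the worked example (5 sources, 20 channels, 500 samples,
$A_{max}=10$, 10 repetitions), the EEG-like design (8 sources, 30 channels,
512 samples, $A_{max}=14$), an accuracy experiment over 10–25 fresh mixing
matrices of the 8-source design, and robustness sweeps over channel count,
signal length, SNR and frequency scale with the 5-source design.  A single
`cw_ica()` call on the 8-source design takes a few seconds on one CPU; the
accuracy harness scales linearly in `n_runs`.

```{r example, eval = FALSE}
src <- simulate_sources(8, 512, seed = 11)
mix <- mix_signals(src, p = 30, seed = 22)
cw_ica(mix$signals, a_max = 14, rep = 10, seed = 1)
```

## Known limitations

* The method needs $p \ge 2q$ channels; the underdetermined regime
  ($p < q$) and dimensions above $\lfloor p/2 \rfloor$ are out of reach by
  construction.
* All backends assume a linear, stationary mixture of at-most-one-Gaussian
  sources; a near-Gaussian source (the smoothed-noise catalog entry) is
  recovered with visibly lower cross-block correlation, which lowers
  $R_{q_{true}}$ without moving the drop.
* The drop rule takes the single largest drop; when reproducibility decays
  over two adjacent steps, single repetitions can vote one dimension high,
  which the modal vote absorbs.
* Estimates on real recordings inherit all of ICA's preprocessing
  sensitivity (filtering, epoch selection, channel rejection); the package
  ingests any delimited channels-by-samples matrix via `read_matrix()` but
  deliberately contains no EEG preprocessing.
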