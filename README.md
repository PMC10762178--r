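# icdim — how many independent components does your signal have?

Independent component analysis (ICA) unmixes `p` observed channels into
statistically independent sources, but every ICA algorithm must be told how
many components `q` to extract.  Too few merges distinct sources
(under-decomposition); too many shreds real sources into noise
(over-decomposition).  For multichannel electrophysiology — scalp EEG
especially, where ICA is the standard tool for separating brain activity
from blinks, muscle and channel noise — the choice of `q` drives everything
downstream, and in practice it is often picked by eye.

`icdim` makes the choice automatic.  Its core estimator is a split-half
reproducibility criterion:

1. Randomly split the `p` channels into two half-blocks **B₁**, **B₂**.
2. For each candidate dimension `q = 2, …, A_max`, run ICA on each block
   separately and form the cross-block Spearman correlation matrix **P′**
   between the two component sets.
3. Score the candidate by
   `R_q = min_{1≤i≤q} max_j |P′_{ji}|` — the worst-matched component's best
   absolute correlation.  Components reflecting true sources reappear in
   both blocks (`R_q ≈ 1`); once `q` exceeds the true dimension at least
   one component is unmatched noise and `R_q` collapses.
4. Locate the collapse with first differences `D_q = R_q − R_{q−1}`: the
   estimate is `q* − 1`, where `q*` minimizes `D_q`.
5. Repeat over `Rep` random splits and report the modal estimate.

Three comparator selectors are included — the Durbin–Watson residual
criterion, the known-source correlation method (`ica_corr_y`), and
ICA-by-Blocks — together with an EEG-like source simulator and a
benchmarking harness.  FastICA, Infomax and JADE backends are provided by
the CRAN `ica` package.

## Worked example

Five simulated sources (sine, sawtooth, square wave, chirp, spike train),
mixed into 20 channels by a random Gaussian matrix:

```r
library(icdim)
src <- simulate_sources(5, 500, seed = 11)
mix <- mix_signals(src, p = 20, seed = 22)
res <- cw_ica(mix$signals, a_max = 10, rep = 10, seed = 1)
res
#> Determination of the number of independent components (cwica + fastica)
#>   q_opt = 5
#>   votes: 5 5 5 5 5 5 5 5 5 5
round(colMeans(res$profile$r_values), 2)
#>    2    3    4    5    6    7    8    9   10
#> 0.54 0.58 0.65 0.97 0.08 0.08 0.08 0.12 0.11
```

All ten random splits vote for 5 components.  The mean reproducibility
profile tells the story: `R_5 ≈ 0.97` (every component found in one
half-block has a near-perfect rank-correlated partner in the other), and
`R_6 ≈ 0.08` — the sixth component is unmatched noise, so the profile
collapses exactly one step past the true dimension.  `res$profile$r_values`
is the per-repetition data behind a signal-correlation plot.

The same interface is available from a shell:

```sh
exec/icdim simulate --sources 5 --channels 20 --length 500 --seed 1 --out mixed.csv
exec/icdim detect --in mixed.csv --method cwica --ica fastica --rep 10 --seed 1 --out result.json
exec/icdim benchmark --q-true 8 --channels 30 --methods cwica,blocks --runs 10 --out report.json
```

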