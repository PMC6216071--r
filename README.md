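# trggc

Nonparametric Granger-Geweke causality (GGC) with time-reversal testing,
plus the simulation machinery needed to probe how directed-connectivity
estimates break — and how to protect them — under three ubiquitous
observation problems in electrophysiology: a shared non-silent reference,
signal-to-noise (SNR) imbalance across channels, and independent or mixed
additive noise.

The package is aimed at researchers analyzing multichannel trial-based
recordings (EEG/LFP-style data) who want frequency-resolved directed
influence estimates they can stress-test, and at methodologists
benchmarking connectivity estimators on ground-truth simulations.

## What it computes

For a trial-based recording, the cross-spectral density matrix is estimated
by the multitaper (DPSS) method, factorized by Wilson's algorithm into a
minimum-phase factor (`S = psi psi*`), transfer function `H(f)` and
innovation covariance `Sigma` — no autoregressive model is fitted. Geweke's
spectral measure for sender *j* and receiver *i* is

    f_{j->i}(f) = ln [ S_ii(f) / ( S_ii(f) - (Sigma_jj - Sigma_ij^2/Sigma_ii) |H_ij(f)|^2 ) ]

in its bivariate (pairwise) form; the conditional form partials out all
remaining channels through a second, reduced factorization and coincides
with the pairwise form for two channels. Two testing variants are built on
top: **net-GGC** (`f_{j->i} - f_{i->j}`) and **tr-GGC**, the difference
between net-GGC on the original and on time-reversed data, rectified at
zero — genuine lagged interactions flip under time reversal while most
observation artifacts do not.

Alongside the estimators, the package ships:

* MVAR network simulators (two-node 40 Hz oscillator network, broadband
  AR(2) networks with arbitrary unidirectional interactions, a three-node
  MVAR(3) demonstration model loaded from a validated config);
* the three corruption models (common reference, per-channel additive
  noise, linearly mixed white/pink noise sources);
* scenario drivers (`run_common_reference()`, `run_additive_noise()`,
  `run_stokes_purdon()`) sweeping corruption strength over a grid with
  replicate summaries (median, 5th/95th percentiles);
* a reader/writer for the trial-epoch `RAT` MAT-file container used by the
  companion rat somatosensory-evoked-potential benchmark, and a synthetic
  SEP-like fixture generator (`generate_synthetic_sep()`);
* a command-line front-end (`exec/trggc`) over the scenario drivers and the
  container I/O.

## Worked example

Simulate a three-node chain (1 drives 2, 2 drives 3), estimate conditional
GGC, and check what survives the time-reversal test:

```r
library(trggc)
m <- snr_network(3, list(c(1, 2), c(2, 3)))
x <- simulate(m, nsim = 100, seed = 3)      # 100 trials x 400 samples, 200 Hz
g <- ggc(x, method = "conditional")
summary(g)
#> Directed influence summary (conditional, testing = none)
#>  receiver sender peak_freq peak_value mean_value
#>         1      2      71.5   0.003726  0.0008819
#>         1      3      36.5   0.003268  0.0006351
#>         2      1      40.5   0.605998  0.0954751
#>         2      3      52.0   0.003361  0.0007947
#>         3      1      22.5   0.004333  0.0008529
#>         3      2      42.0   0.621769  0.0966816
```

The two imposed edges (1→2 and 2→3) carry peak influence ≈ 0.61 and 0.62
near the network's ~41 Hz resonance; every other directed pair sits at the
finite-sample bias floor (≈ 0.004, cf. `ggc_null_bias_bound(100)` ≈ 0.0043).
The time-reversal test keeps only the true directions:

```r
tg <- ggc(x, method = "conditional", testing = "tr")
round(band_mean(tg, c(35, 47)), 4)   # receiver row <- sender column
#>        [,1]  [,2] [,3]
#> [1,] 0.0000 0.000    0
#> [2,] 0.7747 0.000    0
#> [3,] 0.0057 1.173    0
```

Corruption robustness is one call away, e.g. the white common-reference
sweep: `plot(run_common_reference("white", n_repeats = 5, seed = 1),
mode = "tr_ggc", receiver = 1, sender = 2)` shows the spurious direction
pinned to zero around 40 Hz at every mixing weight.

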