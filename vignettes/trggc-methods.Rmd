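---
title: "Nonparametric Granger-Geweke causality with time-reversal testing: models, numerics, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric Granger-Geweke causality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trggc)
```

## The problem

Frequency-resolved directed influence between simultaneously recorded
signals — Granger-Geweke causality (GGC) — is a workhorse of effective
connectivity analysis in electrophysiology. Applied to real recordings it
faces three well-known observation artifacts: a shared, non-silent reference
subtracted from every channel; unequal signal-to-noise ratio (SNR) across
channels; and additive measurement noise, possibly a linear mixture of
common sources. Each can manufacture influence in a direction where none
exists. `trggc` implements the nonparametric GGC estimation chain together
with simulators for all three corruption mechanisms and the time-reversal
test (tr-GGC) that mitigates them, so that the robustness of any analysis
choice can be quantified before it is trusted on data.

## Estimation chain

**Spectral estimation.** The cross-spectral density matrix $S(f)$ of a
trial-based recording is estimated by the multitaper method: each channel of
each trial is demeaned, multiplied by each of the $2NW-1$ discrete prolate
spheroidal (DPSS) tapers, Fourier transformed, and the cross-products are
averaged uniformly over tapers and trials. The default time-bandwidth
product is $NW = 4$ (seven tapers). No zero padding is applied: the grid
step is $F_s/n$ (0.5 Hz for the default 400-sample epochs at 200 Hz) and
the grid runs from 0 to Nyquist. Spectra are stored as one-sided densities
in units$^2$/Hz, doubled at interior frequencies, so that the trapezoid
integral of the diagonal over $[0, F_s/2]$ equals the per-channel variance;
the analytic spectrum of a known model (`analytic_spectrum()`) uses the
identical convention and is directly comparable.

**Factorization.** Wilson's iterative algorithm factorizes $S(f)$ into a
minimum-phase factor $\psi(f)$ with $S = \psi\psi^*$, from which the
transfer function $H = \psi A_0^{-1}$ and innovation covariance
$\Sigma = A_0 A_0^{\top}$ follow ($A_0$ is the zero-lag causal coefficient
of $\psi$). The iteration is
$\psi_{k+1} = \psi_k\,[\psi_k^{-1} S \psi_k^{-*} + I]_+$, where $[\cdot]_+$
retains non-negative lags of the lag expansion.

**Causality.** Geweke's pairwise measure for sender $j$ and receiver $i$ is
$$f_{j\to i}(f) = \ln\frac{S_{ii}(f)}
  {S_{ii}(f) - (\Sigma_{jj} - \Sigma_{ij}^2/\Sigma_{ii})\,|H_{ij}(f)|^2},$$
evaluated from the factorization of each pair's $2\times 2$ spectrum. The
conditional measure partials out the remaining channels: the receiver's
innovation is first decorrelated from all others ($H' = H P^{-1}$, leaving
$\Sigma_{ii}$ unchanged), the reduced system without the sender is
factorized separately ($G$, $\Sigma_R$), and with
$Q = \tilde G^{-1} H'$ (identity row/column embedded at the sender),
$$F_{j\to i\,|\,\text{rest}}(f) =
  \ln\frac{\Sigma_{R,ii}}{|Q_{ii}(f)|^2\,\Sigma_{ii}}.$$
The denominator is the part of the reduced-model innovation spectrum driven
by the receiver's own innovation. With two channels this reduces exactly to
the pairwise measure; the suite enforces agreement to $10^{-6}$ on random
stable models. A naive form of the conditional denominator,
$(Q\Sigma Q^*)_{ii}$, is an identity equal to $\Sigma_{R,ii}$ (the reduced
innovations are white) and yields zero everywhere; the construction above is
the standard correct one.

**Testing variants.** net-GGC is the per-pair difference
$f_{j\to i} - f_{i\to j}$. tr-GGC (difference-based) computes net-GGC on the
recording and on its time-reversed surrogate and takes the difference,
rectified at zero: influence is inferred only where the forward net measure
exceeds the time-reversed one. Genuine lagged interactions flip direction
under time reversal; reference- and noise-driven artifacts largely do not,
so the difference suppresses them. Pre-rectification values are kept for
diagnostics.

## Numerical choices

* **Causal-part operator.** $[\cdot]_+$ keeps lags $0..n/2$, with the lag-0
  coefficient replaced by the upper triangle of half the lag-0
  autocovariance (this pins the factor's rotational freedom — the Newton-step
  normalization) and the lag-$n/2$ coefficient halved, since on an even
  circular grid that lag is its own mirror image under the Hermitian split.
  Without the latter halving the iteration stalls at a plateau around
  $10^{-3}$ relative residual on estimated spectra; with it, convergence is
  quadratic to machine precision.
* **Convergence.** The iteration stops when the maximum over frequency of
  the relative Frobenius change of $\psi$ falls below `tol` (default
  `1e-9`, `max_iter = 100`). Non-convergence warns and is flagged, never
  silent; the scenario drivers collect these events as per-grid-point
  diagnostics.
* **Regularization.** If the input spectrum has a non-positive eigenvalue at
  any frequency (finite-sample estimates can be numerically singular), a
  ridge $10^{-10}\,\overline{\mathrm{diag}}\,I$ is added before factorizing;
  a spectrum still not positive definite is an error.
* **Grid resolution vs pole radius.** The causal lag expansion of the
  minimum-phase factor decays like $r^k$ for pole radius $r$; with $n$ grid
  points only $n/2$ lags are representable, so models with $r$ close to 1
  need a finer grid (e.g. $r = 0.95$ at $n = 128$ leaves a $\sim 3\times
  10^{-2}$ truncation floor; $n = 1024$ resolves it to machine precision).
  The default study conditions ($r \le 0.9$, $n = 400..500$) are
  comfortably resolved.
* **Spectral resolution of derived quantities.** The multitaper estimate
  converges to the taper-window-convolved spectrum, so causality peaks
  estimated at $NW = 4$ are attenuated relative to the raw analytic truth
  (about 20% for the broadband AR(2) benchmark). Oracle comparisons at
  estimation resolution should use `taper_smoothed_spectrum()`; the raw
  analytic route is reserved for validating the factorization/Geweke chain
  itself, where agreement is at the $10^{-6}$ level.
* **Negative values.** Pairwise GGC is non-negative by construction;
  conditional values can dip negative by cross-factorization error at the
  $10^{-12}$ scale and are floored at zero, while anything below $-10^{-6}$
  raises an error as a numerics bug.

## Simulators and corruption models

The generators implement the study conditions of the simulation framework
they reproduce; their defaults are fixed, not tuning knobs.

* **Two-node oscillator network** (`two_node_oscillator()`): MVAR(2), pole
  radius 0.8 and design frequency 40 Hz for both nodes at $F_s = 200$ Hz,
  node 1 driving node 2 with lag-1/lag-2 coefficients $(-0.35, 0.7)$.
  The AR(2) spectral peak sits at
  $\cos\omega = -a_1(1-a_2)/(4a_2)$ — 39.7 Hz for these parameters, which
  rounds to the 40 Hz design value at the 5 Hz granularity used in
  reporting.
* **Broadband AR(2) network** (`snr_network()`): every node
  $x_i(t) = 0.5 x_i(t-1) - 0.8 x_i(t-2) + w_i(t)$, each interaction adding
  $0.2 x_j(t-1) - 0.1 x_j(t-2)$; resonance near 41 Hz.
* **Common reference** (Eq.-style `x' = (1-\alpha)x - \alpha R`): $R$ is
  white with the innovation variance, or an AR(2) oscillator with $r_R =
  0.8$ at 40, 20 or 70 Hz. The weight grid is 0.1..0.9 in steps of 0.1.
* **SNR imbalance / additive noise** (`x' = (1-\alpha)x + \alpha e` on
  selected channels): sources are white, pink, or alternating white/pink
  (odd-indexed white, even-indexed pink — the split is a documented choice,
  as is the mixing matrix's distribution: i.i.d. standard normal entries,
  unit-norm rows, redrawn until the singular-value ratio exceeds
  $10^{-10}$). Pink noise is generated by frequency-domain shaping
  ($f^{-1/2}$ amplitude scaling, DC zeroed, rescaled to unit variance),
  chosen for its exact target slope and determinism.
* **Three-node MVAR(3) demonstration**: coefficients ship as a JSON config
  (`inst/extdata/stokes_purdon_mvar3.json`, transcribed from Stokes &
  Purdon's example rather than hard-coded): pole radii (0.9, 0.7, 0.8) at
  (40, 10, 50) Hz, $F_s = 120$ Hz, couplings $1\to2$ at lag 2 ($-0.356$)
  and $2\to3$ at lag 3 ($-0.3098$), identity innovation covariance. The
  loader validates stability and the three pole frequencies before use.

**Choices the source material leaves open.** Innovations are Gaussian (only
second-order structure matters for GGC); burn-in is 1000 samples from a zero
initial state; each trial's innovations come from a counter-based substream
of the master seed, so trial $k$ is bit-reproducible whatever the total
trial count, and reference/noise streams never collide with node
innovations. The scenario drivers add `n_repeats` independent replicates per
grid point (default 10) summarized by median and 5th/95th percentile
curves; the original framework estimates once per condition, so the
replication is flagged in the configuration echo.

## What the synthetic SEP fixture does and does not emulate

`generate_synthetic_sep()` mimics the *layout* and the *expected causal
skeleton* of the companion whisker-stimulation dataset: 15 channels at
2000 Hz, epochs $-100..+200$ ms, 1/f background, and a damped gamma-band
(60 Hz) stochastic burst on channel 12 from 5 ms post-stimulus that reaches
channels 10 and 14 with a 2 ms lag and 0.6 attenuation — a stationary
narrowband carrier under a time-varying envelope, not a nonstationary MVAR.
It does not emulate volume conduction, per-channel spectra beyond 1/f,
artifacts, or the real dataset's trial-count heterogeneity. Tests passing on
the fixture demonstrate that the I/O and estimation chain detect a known
driver under realistic dimensions; they say nothing about anesthesia
effects, artifact robustness, or the physiological validity of any real-data
conclusion.

## Validation design

Three oracle routes are independent of the estimation chain: closed-form
AR(2) spectral peaks; autocovariances from the companion-form Lyapunov
equation; and Geweke measures evaluated directly from the true transfer
function of a model (no factorization), plus an OLS-fitted MVAR
(`stats::ar.ols`) as a fully separate parametric estimate. The MAT-file
layer is cross-checked against an independent reader/writer (scipy) in both
directions, including compressed elements.

Null calibration uses an empirically tabulated bias floor: null GGC
estimates scale as the reciprocal of (tapers $\times$ trials), with the 95th
percentile near $1.5/(KT)$ and maxima near $5/(KT)$; the packaged bound
`ggc_null_bias_bound()` returns $3/(KT)$.

The acceptance-style checks run at deliberately scaled sizes chosen to keep
the full suite fast while preserving every qualitative ordering: 5
replicates per grid point for the corruption sweeps and 100 realizations for
the MVAR(3) demonstration (medians and orderings are stable at these
sizes; the percentile bands are wider than at full scale).

## Known limitations

* Conditional estimation requires the full spectral matrix to be well
  conditioned; heavily rank-deficient montages rely on the diagonal ridge.
* Only the difference-based time-reversal variant is implemented; the
  interface accepts a variant token so others can be added.
* MAT v7.3 (HDF5) containers are rejected with guidance to re-save as v7;
  complex, sparse, cell and non-scalar struct arrays are outside the
  reader's scope.
* No significance machinery beyond tr-rectification is provided
  (by design); the bias bound is a calibration aid, not a test.
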