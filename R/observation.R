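#' Common reference signal
#'
#' Builds the shared reference series subtracted from every channel in the
#' common-reference corruption model.  `kind = "white"` gives i.i.d. zero-mean
#' noise of the requested variance; `kind = "ar2"` gives a damped stochastic
#' oscillator `R(t) = 2 r_R cos(theta_R) R(t-1) - r_R^2 R(t-2) + w_R(t)` with
#' `theta_R = 2 pi f_R / fs` and innovation variance `variance`.  One
#' realization is drawn per trial, independent of any node innovations (own
#' seed substream).
#'
#' @param kind `"white"` or `"ar2"`.
#' @param n_samples,n_trials dimensions of the reference block.
#' @param fs sampling rate (Hz).
#' @param r_R pole radius for `"ar2"`; default 0.8.
#' @param f_R resonance frequency (Hz) for `"ar2"`; default 40.
#' @param variance innovation (or white-noise) variance; default 1.
#' @param seed master seed.
#' @return object of class `"reference_signal"`: `data`
#'   (`n_samples x n_trials`), `kind`, `fs`, `params`.
#' @export
make_reference <- function(kind = c("white", "ar2"), n_samples, n_trials,
                           fs, r_R = 0.8, f_R = 40, variance = 1, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "ar2" && !(r_R > 0 && r_R < 1 && f_R > 0 && f_R < fs / 2))
    stop_trggc("need 0 < r_R < 1 and 0 < f_R < fs/2")
  data <- matrix(0, n_samples, n_trials)
  if (kind == "white") {
    for (k in seq_len(n_trials)) {
      set.seed(substream_seed(seed, "reference", k))
      data[, k] <- rnorm(n_samples, sd = sqrt(variance))
    }
  } else {
    burn <- 1000L
    a <- ar2_self(r_R, f_R, fs)
    for (k in seq_len(n_trials)) {
      set.seed(substream_seed(seed, "reference", k))
      w <- rnorm(n_samples + burn, sd = sqrt(variance))
      r <- numeric(n_samples + burn)
      r[1] <- w[1]; r[2] <- a[1] * r[1] + w[2]
      for (t in 3:(n_samples + burn))
        r[t] <- a[1] * r[t - 1] + a[2] * r[t - 2] + w[t]
      data[, k] <- r[burn + seq_len(n_samples)]
    }
  }
  structure(list(data = data, kind = kind, fs = fs,
                 params = list(r_R = r_R, f_R = f_R, variance = variance)),
            class = "reference_signal")
}

#' Corrupt a recording with a common reference
#'
#' Implements the common-reference observation model: every channel i of
#' every trial becomes
#' `x'_i(t) = (1 - alpha) * x_i(t) - alpha * R(t)` with the same reference
#' series R subtracted from all channels of a trial, so the ratio
#' `alpha / (1 - alpha)` controls how strongly the (non-silent) reference
#' contaminates the observations.
#'
#' @param X a [trials_array()].
#' @param R a [make_reference()] output with matching dimensions and `fs`.
#' @param alpha mixing weight in `[0, 1]`; `alpha = 0` returns `X` unchanged.
#' @return corrupted [trials_array()].
#' @export
apply_common_reference <- function(X, R, alpha) {
  stopifnot(inherits(X, "trials_array"), inherits(R, "reference_signal"))
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha <= 1))
    stop_trggc("'alpha' must lie in [0, 1]")
  d <- dim(X$data)
  if (nrow(R$data) != d[1] || ncol(R$data) != d[3] ||
      abs(R$fs - X$fs) > 1e-9)
    stop_trggc("reference and data dimensions / sampling rates differ")
  out <- X
  Rexp <- aperm(array(R$data, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  out$data <- (1 - alpha) * X$data - alpha * Rexp
  out
}

# unit-variance pink (1/f) noise via frequency-domain shaping: scale the
# discrete spectrum of white noise by f^(-1/2) (DC zeroed), invert, rescale
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  k <- 0:(n - 1)
  fidx <- pmin(k, n - k)                  # |frequency| index, symmetric
  sc <- ifelse(fidx == 0, 0, 1 / sqrt(fidx))
  x <- Re(fft(W * sc, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Ensemble of independent or mixed additive-noise sources
#'
#' Draws `S_count` independent noise sources per trial (white, pink, or an
#' alternating white/pink mixture: odd-indexed sources white, even-indexed
#' pink) and mixes them into `M` channel-noise series through a linear mixing
#' matrix `K` (`M x S`): `E(t) = K eta(t)`.  `K` is the identity
#' (independent noise), a random full-rank matrix with i.i.d. standard-normal
#' entries and unit-norm rows (redrawn until the singular-value ratio exceeds
#' `1e-10`), or user-given.
#'
#' @param M number of channels.
#' @param S_count number of sources; identity mixing requires `S_count = M`.
#' @param color `"white"`, `"pink"` or `"white+pink"`.
#' @param K_mode `"identity"`, `"random_full_rank"` or `"given"`.
#' @param K mixing matrix when `K_mode = "given"` (must be full rank if
#'   `M <= S_count`).
#' @param n_samples,n_trials dimensions.
#' @param fs sampling rate (Hz).
#' @param seed master seed (sources and K use separate substreams).
#' @return object of class `"noise_ensemble"`: `sources`
#'   (`n x S x trials`), `K`, `data` (mixed noise, `n x M x trials`),
#'   `color`, `fs`, `channel_variance`.
#' @export
make_noise_ensemble <- function(M, S_count = M,
                                color = c("white", "pink", "white+pink"),
                                K_mode = c("identity", "random_full_rank",
                                           "given"),
                                K = NULL, n_samples, n_trials, fs, seed = 1) {
  color <- match.arg(color)
  K_mode <- match.arg(K_mode)
  if (K_mode == "identity") {
    if (S_count != M) stop_trggc("identity mixing requires S_count = M")
    K <- diag(M)
  } else if (K_mode == "random_full_rank") {
    set.seed(substream_seed(seed, "mixing", 0L))
    repeat {
      K <- matrix(rnorm(M * S_count), M, S_count)
      K <- K / sqrt(rowSums(K^2))
      sv <- svd(K, nu = 0, nv = 0)$d
      if (sv[min(M, S_count)] / sv[1] > 1e-10) break
    }
  } else {
    if (is.null(K) || !is.matrix(K) || nrow(K) != M || ncol(K) != S_count)
      stop_trggc("'K' must be an M x S matrix")
    sv <- svd(K, nu = 0, nv = 0)$d
    if (sv[min(M, S_count)] / sv[1] <= 1e-10)
      stop_trggc("'K' is rank deficient")
  }
  src <- array(0, dim = c(n_samples, S_count, n_trials))
  for (k in seq_len(n_trials)) {
    set.seed(substream_seed(seed, "noise_sources", k))
    for (s in seq_len(S_count)) {
      pink <- switch(color, white = FALSE, pink = TRUE,
                     "white+pink" = (s %% 2 == 0))
      src[, s, k] <- if (pink) pink_noise(n_samples) else rnorm(n_samples)
    }
  }
  E <- array(0, dim = c(n_samples, M, n_trials))
  for (k in seq_len(n_trials))
    E[, , k] <- matrix(src[, , k], n_samples, S_count) %*% t(K)
  structure(list(sources = src, K = K, data = E, color = color, fs = fs,
                 channel_variance = apply(E, 2, stats::var)),
            class = "noise_ensemble")
}

#' Superimpose additive observation noise on selected channels
#'
#' Implements the additive-noise observation model: for each selected
#' channel c, `x'_c(t) = (1 - alpha) * x_c(t) + alpha * e_c(t)`; unselected
#' channels are copied unchanged.  The signal-to-noise ratio of a corrupted
#' channel is proportional to `(1 - alpha) / alpha`.
#'
#' @param X a [trials_array()].
#' @param E a [make_noise_ensemble()] with M matching channels of `X`.
#' @param alpha mixing weight in `[0, 1]`.
#' @param channels non-empty subset of channels to corrupt; default all.
#' @return corrupted [trials_array()].
#' @export
apply_additive_noise <- function(X, E, alpha, channels = NULL) {
  stopifnot(inherits(X, "trials_array"), inherits(E, "noise_ensemble"))
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0 && alpha <= 1))
    stop_trggc("'alpha' must lie in [0, 1]")
  d <- dim(X$data)
  de <- dim(E$data)
  if (de[1] != d[1] || de[2] != d[2] || de[3] != d[3])
    stop_trggc("noise ensemble dimensions do not match the data")
  channels <- channels %||% seq_len(d[2])
  if (length(channels) == 0 || any(channels < 1 | channels > d[2]))
    stop_trggc("'channels' must be a non-empty subset of 1..M")
  out <- X
  out$data[, channels, ] <- (1 - alpha) * X$data[, channels, , drop = FALSE] +
    alpha * E$data[, channels, , drop = FALSE]
  out
}
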