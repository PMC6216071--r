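#' Frequency-indexed cross-spectral density matrix
#'
#' Container for one-sided cross-spectral density matrices on an ascending
#' frequency grid from 0 to Nyquist.  Entries are in units^2/Hz; interior
#' frequencies carry the doubled (one-sided) density while the DC and Nyquist
#' bins carry the plain two-sided density, so the trapezoid integral of the
#' diagonal over `[0, fs/2]` recovers the per-channel process variance.
#'
#' @param freqs ascending frequency grid (Hz), from 0 up to Nyquist.
#' @param S complex array `M x M x length(freqs)`; Hermitian at each
#'   frequency with real non-negative diagonal.
#' @param fs sampling rate (Hz).
#' @param meta list of estimation metadata (NW, n_tapers, n_trials, ...).
#' @return object of class `"spectral_matrix"`.
#' @seealso [multitaper_csd()], [analytic_spectrum()], [wilson_factorize()]
#' @export
spectral_matrix <- function(freqs, S, fs, meta = list()) {
  if (!is.array(S) || length(dim(S)) != 3L || dim(S)[1] != dim(S)[2])
    stop_trggc("'S' must be an M x M x F complex array")
  if (dim(S)[3] != length(freqs))
    stop_trggc("third dimension of 'S' must match 'freqs'")
  if (is.unsorted(freqs)) stop_trggc("'freqs' must be ascending")
  M <- dim(S)[1]
  # structural checks: Hermitian, real non-negative diagonal
  for (fi in seq_along(freqs)) {
    Sf <- S[, , fi]
    if (max(Mod(Sf - Conj(t(Sf)))) > 1e-8 * max(1e-300, max(Mod(Sf))))
      stop_trggc(sprintf("S not Hermitian at %g Hz", freqs[fi]))
  }
  dg <- Re(apply(S, 3, diag))
  if (min(dg) < -1e-10 * max(abs(dg)))
    stop_trggc("negative power on the spectral diagonal")
  structure(list(freqs = as.numeric(freqs), S = S, fs = fs, M = M,
                 meta = meta),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("spectral_matrix: %d channels, %d frequencies (%g-%g Hz), Fs = %g Hz\n",
              x$M, length(x$freqs), min(x$freqs), max(x$freqs), x$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.spectral_matrix <- function(x, ...) {
  M <- x$M; F <- length(x$freqs)
  idx <- expand.grid(i = seq_len(M), j = seq_len(M), f = seq_len(F))
  data.frame(frequency = x$freqs[idx$f], i = idx$i, j = idx$j,
             re = Re(x$S[cbind(idx$i, idx$j, idx$f)]),
             im = Im(x$S[cbind(idx$i, idx$j, idx$f)]))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, as the leading eigenvectors of the standard symmetric
#' tridiagonal matrix whose eigenvectors are the Slepian sequences.  Tapers
#' have unit energy and form an orthonormal set; polarity follows the common
#' convention (symmetric tapers have positive mean, antisymmetric tapers
#' start positive).
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product (e.g. 4).
#' @param k number of tapers; default `2 * nw - 1`.
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k = 2 * nw - 1) {
  if (!(is_count(n, 8))) stop_trggc("'n' must be an integer >= 8")
  if (!(nw >= 1)) stop_trggc("'nw' must be >= 1")
  k <- as.integer(k)
  if (k < 1 || k > n) stop_trggc("'k' must be in 1..n")
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .trggc_cache[[key]]
  if (!is.null(cached)) return(cached)
  W <- nw / n
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  e <- t0[-1] * (n - t0[-1]) / 2
  Tm <- diag(d)
  Tm[cbind(1:(n - 1), 2:n)] <- e
  Tm[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(Tm, symmetric = TRUE)
  H <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h <- H[, j]
    if (abs(mean(h)) > 1e-8) {
      if (mean(h) < 0) H[, j] <- -h
    } else {
      # antisymmetric taper: make the initial lobe positive
      nz <- which(abs(h) > max(abs(h)) * 1e-3)[1]
      if (h[nz] < 0) H[, j] <- -h
    }
  }
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  .trggc_cache[[key]] <- H
  H
}

#' Multitaper cross-spectral density estimate over trials
#'
#' Estimates the one-sided cross-spectral density matrix of a trial-based
#' recording by the multitaper method: each channel of each trial is
#' demeaned, multiplied by each DPSS taper, Fourier transformed, and the
#' cross-products are averaged uniformly over tapers and trials.  No zero
#' padding is applied, so the frequency grid step is `fs / n_samples` and the
#' grid runs from 0 to Nyquist.
#'
#' @param X a [trials_array()].
#' @param nw time-bandwidth product; default 4 (7 tapers).
#' @param n_tapers number of tapers; default `2 * nw - 1`.
#' @return a [spectral_matrix()] with estimation metadata.
#' @examples
#' x <- simulate(two_node_oscillator(), nsim = 20, seed = 1)
#' S <- multitaper_csd(x, nw = 4)
#' S$freqs[which.max(Re(S$S[1, 1, ]))]
#' @export
multitaper_csd <- function(X, nw = 4, n_tapers = NULL) {
  stopifnot(inherits(X, "trials_array"))
  if (anyNA(X$data)) stop_trggc("input contains NA/NaN")
  n <- n_samples_of(X); M <- n_channels(X); K <- n_trials(X)
  if (!(nw >= 1)) stop_trggc("'nw' must be >= 1")
  if (n <= 2 * nw) stop_trggc("need n_samples > 2 * NW")
  nt <- as.integer(n_tapers %||% (2 * nw - 1))
  H <- dpss_tapers(n, nw, nt)
  fs <- X$fs
  nf <- floor(n / 2) + 1L
  freqs <- (0:(nf - 1)) * fs / n
  # demean per trial and channel
  xm <- X$data
  mu <- colMeans(xm)                      # M x K means
  xm <- xm - rep(mu, each = n)
  flat <- matrix(xm, n, M * K)
  acc <- array(complex(real = 0), dim = c(M, M, nf))
  for (tp in seq_len(nt)) {
    Z <- mvfft(flat * H[, tp])
    Z <- Z[seq_len(nf), , drop = FALSE]
    dim(Z) <- c(nf, M, K)
    for (fi in seq_len(nf)) {
      Zm <- matrix(Z[fi, , ], M, K)
      acc[, , fi] <- acc[, , fi] + Zm %*% Conj(t(Zm))
    }
  }
  acc <- acc / (nt * K * fs)              # two-sided density
  # one-sided convention: double interior bins
  even <- n %% 2 == 0
  for (fi in seq_len(nf)) {
    interior <- fi > 1 && !(even && fi == nf)
    if (interior) acc[, , fi] <- 2 * acc[, , fi]
    acc[, , fi] <- (acc[, , fi] + Conj(t(acc[, , fi]))) / 2
  }
  spectral_matrix(freqs, acc, fs,
                  meta = list(NW = nw, n_tapers = nt, n_trials = K,
                              n_samples = n, source = "multitaper"))
}

#' Expected multitaper spectrum of a known cross-spectral density
#'
#' Convolves a one-sided cross-spectral matrix with the average spectral
#' window of the DPSS taper set, giving the spectrum that
#' [multitaper_csd()] converges to as trials grow.  Sharp spectral peaks are
#' attenuated by the taper bandwidth `NW * fs / n`, so quantities derived
#' from estimated spectra (e.g. causality at a resonance) should be compared
#' against this resolution-matched version of the truth rather than the raw
#' analytic spectrum.
#'
#' @param S a [spectral_matrix()] on the regular 0..Nyquist FFT grid.
#' @param nw time-bandwidth product of the taper set.
#' @param n_tapers number of tapers; default `2 * nw - 1`.
#' @return a [spectral_matrix()] of the same shape.
#' @export
taper_smoothed_spectrum <- function(S, nw = 4, n_tapers = NULL) {
  C <- twosided_power_cube(S)
  n <- dim(C)[3]
  nt <- as.integer(n_tapers %||% (2 * nw - 1))
  H <- dpss_tapers(n, nw, nt)
  W <- rowMeans(Mod(mvfft(H))^2)
  W <- W / sum(W)
  Wf <- fft(W)
  conv_circ <- function(v) Re(fft(fft(v) * Wf, inverse = TRUE)) / n
  M <- S$M
  nf <- length(S$freqs)
  fs <- S$fs
  at_nyq <- abs(S$freqs[nf] - fs / 2) < 1e-6 * fs
  S1 <- array(complex(real = 0), dim = c(M, M, nf))
  for (i in seq_len(M)) for (j in seq_len(M)) {
    sm <- complex(real = conv_circ(Re(C[i, j, ])),
                  imaginary = conv_circ(Im(C[i, j, ])))
    fac <- ifelse(seq_len(nf) == 1 | (at_nyq & seq_len(nf) == nf), fs, fs / 2)
    S1[i, j, ] <- sm[seq_len(nf)] / fac
  }
  for (fi in seq_len(nf)) S1[, , fi] <- (S1[, , fi] + Conj(t(S1[, , fi]))) / 2
  spectral_matrix(S$freqs, S1, fs,
                  meta = c(S$meta, list(smoothed_nw = nw)))
}

# Rebuild the full circular (two-sided, power-scale) spectral cube from a
# one-sided spectral_matrix whose grid is the regular fft grid.  Returns an
# M x M x n complex array with S_pow(f) = H Sigma H^* scale (density * fs).
# An even underlying sample count puts the last bin exactly at Nyquist
# (undoubled); an odd count ends one half-step short of Nyquist (doubled).
twosided_power_cube <- function(S) {
  freqs <- S$freqs; fs <- S$fs
  nf <- length(freqs)
  step <- freqs[2] - freqs[1]
  if (abs(freqs[1]) > 1e-9 || any(abs(diff(freqs) - step) > 1e-6 * step))
    stop_trggc("factorization needs a regular frequency grid starting at 0")
  at_nyq <- abs(freqs[nf] - fs / 2) < 1e-6 * fs
  n <- if (at_nyq) 2L * (nf - 1L) else 2L * nf - 1L
  if (abs(n * step - fs) > 1e-6 * fs)
    stop_trggc("frequency grid step inconsistent with a 0..Nyquist fft grid")
  M <- S$M
  C <- array(complex(real = 0), dim = c(M, M, n))
  for (fi in seq_len(nf)) {
    fac <- if (fi == 1 || (at_nyq && fi == nf)) fs else fs / 2
    C[, , fi] <- S$S[, , fi] * fac
  }
  last_mirrored <- if (at_nyq) nf - 1L else nf
  for (fi in 2:last_mirrored) C[, , n - fi + 2] <- Conj(C[, , fi])
  C
}
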