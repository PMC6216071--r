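#' Multivariate autoregressive (MVAR) model objects
#'
#' An MVAR(p) model for an M-channel process with the sign convention
#' \deqn{x(t) = \sum_{k=1}^{p} A_k x(t-k) + w(t),}
#' where the innovations \eqn{w(t)} are zero-mean white noise with covariance
#' \eqn{\Sigma_w}.  The object is the generative core of every simulation in
#' the package and also admits an exact (analytic) cross-spectral density via
#' [analytic_spectrum()].
#'
#' @param A coefficient array, either an `M x M x p` array or a list of `p`
#'   `M x M` matrices (`A[[k]]` multiplies `x(t-k)`).  `p = 0` (white noise)
#'   is allowed via an `M x M x 0` array or an empty list.
#' @param sigma innovation covariance `M x M`, symmetric positive definite.
#'   Defaults to the identity.
#' @param fs sampling rate in Hz.
#'
#' @return An object of class `"mvar_model"` with elements `A` (array),
#'   `Sigma`, `fs`, `M`, `p`.
#'
#' @details Construction fails unless `sigma` admits a Cholesky factorization
#' and the companion-form spectral radius is strictly below 1 (stability);
#' the error message reports the offending radius.
#'
#' @seealso [two_node_oscillator()], [snr_network()], [simulate.mvar_model()],
#'   [analytic_spectrum()]
#' @examples
#' m <- mvar_model(list(matrix(0.5, 1, 1)), fs = 1)
#' m$p
#' @export
mvar_model <- function(A, sigma = NULL, fs = 1) {
  if (is.list(A)) {
    p <- length(A)
    if (p > 0) {
      M <- nrow(A[[1]])
      A <- array(unlist(A), dim = c(M, M, p))
    } else {
      stop_trggc("for an order-0 model pass an M x M x 0 array, not list()")
    }
  }
  if (!is.array(A) || length(dim(A)) != 3L || dim(A)[1] != dim(A)[2])
    stop_trggc("'A' must be an M x M x p array or list of square matrices")
  M <- dim(A)[1]
  p <- dim(A)[3]
  if (p > 0 && !all(is.finite(A)))
    stop_trggc("all coefficient matrices must be finite")
  if (is.null(sigma)) sigma <- diag(M)
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-10)))
    stop_trggc("'sigma' must be symmetric")
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop_trggc("'sigma' must be positive definite (Cholesky failed)")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0))
    stop_trggc("'fs' must be a positive scalar sampling rate in Hz")
  m <- structure(list(A = A, Sigma = (sigma + t(sigma)) / 2, fs = fs,
                      M = M, p = p),
                 class = "mvar_model")
  rho <- companion_spectral_radius(m)
  if (rho >= 1)
    stop_trggc(sprintf(
      "unstable MVAR model: companion spectral radius %.6f >= 1", rho))
  m
}

#' Spectral radius of the companion matrix of an MVAR model
#'
#' @param model an [mvar_model()].
#' @return Largest eigenvalue modulus of the `p*M x p*M` companion matrix;
#'   0 for an order-0 model.  Values below 1 mean the model is stable.
#' @export
companion_spectral_radius <- function(model) {
  M <- model$M; p <- model$p
  if (p == 0) return(0)
  C <- matrix(0, p * M, p * M)
  for (k in seq_len(p)) C[1:M, ((k - 1) * M + 1):(k * M)] <- model$A[, , k]
  if (p > 1) C[(M + 1):(p * M), 1:((p - 1) * M)] <- diag((p - 1) * M)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR(%d) model: %d channel%s, Fs = %g Hz\n", x$p, x$M,
              if (x$M == 1) "" else "s", x$fs))
  cat(sprintf("  companion spectral radius: %.4f\n",
              companion_spectral_radius(x)))
  cat("  innovation covariance diag:",
      paste(signif(diag(x$Sigma), 4), collapse = ", "), "\n")
  invisible(x)
}

# AR(2) self terms [2 r cos(theta), -r^2] for a pole radius r and resonance
# f Hz at sampling rate fs
ar2_self <- function(r, f, fs) {
  theta <- 2 * pi * f / fs
  c(2 * r * cos(theta), -r^2)
}

#' Two-node unidirectionally coupled oscillator network
#'
#' Builds the canonical MVAR(2) benchmark network of two damped stochastic
#' oscillators in which node 1 drives node 2.  Each node has self terms
#' `[2 r cos(theta), -r^2]` with `theta = 2 pi f / fs`, so the poles sit at
#' radius `r` and design frequency `f`; node 2 additionally receives node 1
#' through lag-1/lag-2 coefficients `coupling`.
#'
#' @param r1,r2 pole radii in (0, 1); default 0.8.
#' @param f1,f2 design (resonance) frequencies in Hz; default 40.
#' @param fs sampling rate in Hz; default 200.
#' @param coupling two coefficients for the influence of node 1 on node 2 at
#'   lags 1 and 2; default `c(-0.35, 0.7)`.
#' @param sigma innovation covariance (default identity).
#' @return An [mvar_model()] with `M = 2`, `p = 2`.
#' @examples
#' m <- two_node_oscillator()
#' m$A[1, 1, 1]  # 2 * 0.8 * cos(0.4 * pi)
#' @export
two_node_oscillator <- function(r1 = 0.8, r2 = 0.8, f1 = 40, f2 = 40,
                                fs = 200, coupling = c(-0.35, 0.7),
                                sigma = NULL) {
  for (r in c(r1, r2)) if (!(r > 0 && r < 1))
    stop_trggc("pole radii must lie in (0, 1)")
  for (f in c(f1, f2)) if (!(f > 0 && f < fs / 2))
    stop_trggc("design frequencies must lie in (0, fs/2)")
  s1 <- ar2_self(r1, f1, fs); s2 <- ar2_self(r2, f2, fs)
  # rows are receivers: A1[2,1] couples x1(t-1) into x2(t)
  A1 <- matrix(0, 2, 2); A2 <- matrix(0, 2, 2)
  A1[1, 1] <- s1[1]; A2[1, 1] <- s1[2]
  A1[2, 2] <- s2[1]; A2[2, 2] <- s2[2]
  A1[2, 1] <- coupling[1]; A2[2, 1] <- coupling[2]
  mvar_model(list(A1, A2), sigma = sigma, fs = fs)
}

#' Broadband AR(2) network with configurable unidirectional interactions
#'
#' Builds the M-node MVAR(2) network in which every node has self terms
#' `[0.5, -0.8]` and each interaction `(source j, target i)` adds cross terms
#' `[0.2, -0.1]` at lags 1 and 2.  With `M = 2` and a single interaction
#' `(1, 2)` this is the classic two-node SNR-imbalance benchmark model.
#'
#' @param M number of channels (>= 2).
#' @param interactions list of integer pairs `c(source, target)` (or a
#'   two-column matrix, one row per interaction).  Each target may receive at
#'   most one source.
#' @param fs sampling rate in Hz; default 200.
#' @param sigma innovation covariance (default identity).
#' @return An [mvar_model()] with order 2.
#' @examples
#' m <- snr_network(2, list(c(1, 2)))
#' m$A[, , 1]   # [[0.5, 0], [0.2, 0.5]]
#' @export
snr_network <- function(M, interactions = list(), fs = 200, sigma = NULL) {
  if (!is_count(M, 2)) stop_trggc("'M' must be an integer >= 2")
  if (is.matrix(interactions))
    interactions <- lapply(seq_len(nrow(interactions)),
                           function(i) interactions[i, ])
  A1 <- diag(0.5, M); A2 <- diag(-0.8, M)
  targets_seen <- integer(0)
  for (pr in interactions) {
    j <- pr[1]; i <- pr[2]
    if (!(is_count(j) && is_count(i) && j <= M && i <= M))
      stop_trggc("interaction references a channel outside 1..M")
    if (i == j) stop_trggc("interaction source and target must differ")
    if (i %in% targets_seen)
      stop_trggc("each target may receive at most one source")
    targets_seen <- c(targets_seen, i)
    A1[i, j] <- 0.2; A2[i, j] <- -0.1
  }
  mvar_model(list(A1, A2), sigma = sigma, fs = fs)
}

#' Simulate trials from an MVAR model
#'
#' Generates `nsim` independent trials of Gaussian-innovation data from a
#' stable [mvar_model()].  Each trial draws its innovations from a dedicated
#' substream of the master seed (a counter-based scheme), so trial k is
#' reproduced bit-identically whatever the total number of trials requested.
#' A burn-in stretch started from a zero state is discarded to remove the
#' transient.
#'
#' @param object an [mvar_model()].
#' @param nsim number of trials; default 100.
#' @param seed master seed (integer); required for reproducibility, default 1.
#' @param n_samples samples per trial after burn-in; default 400.
#' @param burn_in initial samples discarded per trial; default 1000.
#' @param ... unused.
#' @return A [trials_array()] of dimension `n_samples x M x nsim`.
#' @examples
#' x <- simulate(two_node_oscillator(), nsim = 5, seed = 1, n_samples = 100)
#' dim(x$data)
#' @export
simulate.mvar_model <- function(object, nsim = 100, seed = 1,
                                n_samples = 400, burn_in = 1000, ...) {
  model <- object
  if (!is_count(nsim)) stop_trggc("'nsim' must be a positive integer")
  if (!is_count(n_samples, max(1L, model$p)))
    stop_trggc("'n_samples' must be >= the model order")
  if (!(is_count(burn_in, 0))) stop_trggc("'burn_in' must be >= 0")
  M <- model$M; p <- model$p
  n_tot <- n_samples + burn_in
  L <- chol(model$Sigma)                      # Sigma = t(L) %*% L
  # per-trial innovations from counter-based substreams
  W <- array(0, dim = c(n_tot, M, nsim))
  for (k in seq_len(nsim)) {
    set.seed(substream_seed(seed, "innovations", k))
    W[, , k] <- matrix(rnorm(n_tot * M), n_tot, M) %*% L
  }
  X <- array(0, dim = c(n_tot, M, nsim))
  if (p == 0) {
    X <- W
  } else {
    for (t in seq_len(n_tot)) {
      acc <- matrix(W[t, , ], M, nsim)
      for (k in seq_len(min(p, t - 1))) {
        acc <- acc + model$A[, , k] %*% matrix(X[t - k, , ], M, nsim)
      }
      X[t, , ] <- acc
    }
  }
  out <- X[burn_in + seq_len(n_samples), , , drop = FALSE]
  trials_array(out, fs = model$fs,
               times = (seq_len(n_samples) - 1) / model$fs,
               time_unit = "s")
}

#' Exact cross-spectral density of an MVAR model
#'
#' Evaluates the analytic one-sided cross-spectral matrix
#' \eqn{S(f) = H(f) \Sigma_w H(f)^* / F_s} (doubled at interior frequencies)
#' with transfer function
#' \eqn{H(f) = (I - \sum_k A_k e^{-i 2 \pi f k / F_s})^{-1}}.  The
#' normalization matches [multitaper_csd()] exactly, so the analytic spectrum
#' is a direct oracle for the nonparametric chain.
#'
#' @param model an [mvar_model()].
#' @param freqs frequency grid in Hz, inside `[0, fs/2]`.  Default: the grid
#'   of an `n_samples`-point FFT truncated at Nyquist.
#' @param n_samples grid size used when `freqs` is NULL; default 400.
#' @return A [spectral_matrix] object.
#' @examples
#' S <- analytic_spectrum(two_node_oscillator(), n_samples = 200)
#' S$freqs[which.max(Re(S$S[1, 1, ]))]  # close to 39.7 Hz
#' @export
analytic_spectrum <- function(model, freqs = NULL, n_samples = 400) {
  fs <- model$fs
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = fs / n_samples)
  if (any(freqs < 0 | freqs > fs / 2 + 1e-9))
    stop_trggc("'freqs' must lie in [0, fs/2]")
  M <- model$M
  S <- array(complex(real = 0), dim = c(M, M, length(freqs)))
  I <- diag(M)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    Af <- I * (1 + 0i)
    for (k in seq_len(model$p))
      Af <- Af - model$A[, , k] * exp(-2i * pi * f * k / fs)
    H <- tryCatch(solve(Af), error = function(e)
      stop_trggc(sprintf("transfer function singular at %g Hz", f)))
    Sf <- H %*% model$Sigma %*% Conj(t(H)) / fs
    fac <- if (f < 1e-12 || abs(f - fs / 2) < 1e-9) 1 else 2
    S[, , fi] <- fac * (Sf + Conj(t(Sf))) / 2
  }
  spectral_matrix(freqs, S, fs,
                  meta = list(source = "analytic", n_samples = n_samples))
}

#' Transfer function and innovation covariance of an MVAR model
#'
#' @param model an [mvar_model()].
#' @param freqs frequencies (Hz).
#' @return list with `H` (`M x M x F` complex) and `Sigma`.
#' @keywords internal
#' @noRd
mvar_transfer <- function(model, freqs) {
  M <- model$M
  H <- array(complex(real = 0), dim = c(M, M, length(freqs)))
  I <- diag(M)
  for (fi in seq_along(freqs)) {
    Af <- I * (1 + 0i)
    for (k in seq_len(model$p))
      Af <- Af - model$A[, , k] * exp(-2i * pi * freqs[fi] * k / model$fs)
    H[, , fi] <- solve(Af)
  }
  list(H = H, Sigma = model$Sigma)
}

#' Serialize an MVAR model to JSON
#'
#' Writes a plain key-value JSON file holding `M`, `p`, the coefficient
#' matrices, the innovation covariance and the sampling rate, readable by
#' [read_mvar_json()].
#'
#' @param model an [mvar_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mvar_json <- function(model, path) {
  obj <- list(M = model$M, p = model$p, fs = model$fs,
              A = lapply(seq_len(model$p), function(k)
                unname(as.matrix(model$A[, , k]))),
              Sigma = unname(model$Sigma))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mvar_json
#' @export
read_mvar_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$p
  M <- obj$M
  A <- array(0, c(M, M, p))
  if (p > 0) {
    if (is.list(obj$A)) {
      for (k in seq_len(p)) A[, , k] <- as.matrix(obj$A[[k]])
    } else {
      # jsonlite simplifies a list of equal-sized matrices to a k x i x j array
      A <- aperm(obj$A, c(2, 3, 1))
    }
  }
  mvar_model(A, sigma = as.matrix(obj$Sigma), fs = obj$fs)
}
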