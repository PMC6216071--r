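#' Wilson's spectral matrix factorization
#'
#' Decomposes a one-sided Hermitian positive-definite cross-spectral density
#' matrix into its minimum-phase factor by Wilson's iterative algorithm,
#' yielding the transfer function `H(f)` and the innovation covariance
#' `Sigma` that underlie nonparametric Granger-Geweke causality.
#'
#' The iteration operates on the full circular frequency grid rebuilt from
#' the one-sided input: `psi` is initialized as the (constant-in-frequency)
#' Cholesky factor of the frequency-averaged spectrum and updated as
#' `psi <- psi * [psi^-1 S psi^-H + I]_+`, where `[]_+` keeps the causal part
#' of the lag expansion with half weight at lag zero.  Convergence is declared
#' when the maximum over frequency of the relative Frobenius change of `psi`
#' drops below `tol`.
#'
#' When the smallest eigenvalue of the input at any frequency is non-positive
#' (finite-sample estimates can be numerically singular), a diagonal ridge
#' `delta * mean(diag) * I` with `delta = 1e-10` is added before factorizing.
#'
#' @param S a [spectral_matrix()] on the regular FFT grid from 0 to Nyquist.
#' @param tol relative convergence tolerance; default `1e-9`.
#' @param max_iter maximum number of iterations; default 100.
#' @return An object of class `"spectral_factorization"`: a list with
#'   \describe{
#'     \item{psi}{minimum-phase factor, `M x M x F` (one-sided grid), on the
#'       power scale `S_pow = psi psi^H` with `S_pow = fs * S / 2` at interior
#'       frequencies.}
#'     \item{H}{transfer function `psi %*% solve(A0)`, `M x M x F`.}
#'     \item{Sigma}{innovation covariance `A0 A0'` (natural units^2).}
#'     \item{residual}{max over f of relative Frobenius error
#'       `||S - psi psi^H|| / ||S||`.}
#'     \item{iterations, converged}{iteration diagnostics.}
#'   }
#'   Non-convergence raises a warning (never silent) and is flagged in
#'   `converged`.
#' @examples
#' S <- analytic_spectrum(snr_network(2, list(c(1, 2))), n_samples = 128)
#' f <- wilson_factorize(S, tol = 1e-12)
#' f$Sigma        # close to identity
#' @export
wilson_factorize <- function(S, tol = 1e-9, max_iter = 100) {
  stopifnot(inherits(S, "spectral_matrix"))
  C <- twosided_power_cube(S)
  n <- dim(C)[3]; M <- dim(C)[1]
  nf <- length(S$freqs)
  # eigenvalue floor check + optional ridge
  mind <- Inf; mdiag <- 0
  for (fi in seq_len(nf)) {
    ev <- eigen((C[, , fi] + Conj(t(C[, , fi]))) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    mind <- min(mind, min(ev))
    mdiag <- mdiag + mean(Re(diag(matrix(C[, , fi], M, M))))
  }
  mdiag <- mdiag / nf
  if (mind <= 0) {
    ridge <- 1e-10 * mdiag
    for (fi in seq_len(n)) C[, , fi] <- C[, , fi] + diag(ridge, M)
    ev2 <- min(vapply(seq_len(nf), function(fi)
      min(eigen((C[, , fi] + Conj(t(C[, , fi]))) / 2, symmetric = TRUE,
                only.values = TRUE)$values), numeric(1)))
    if (ev2 <= 0)
      stop_trggc("spectral matrix not positive definite after regularization")
  }
  res <- .wilson_cpp(C, tol, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf(
      "Wilson factorization did not converge in %d iterations (residual %.3g)",
      res$iterations, res$residual), call. = FALSE)
  A0 <- res$A0
  A0inv <- solve(A0)
  psi <- res$psi[, , seq_len(nf), drop = FALSE]
  H <- array(complex(real = 0), dim = dim(psi))
  for (fi in seq_len(nf)) H[, , fi] <- psi[, , fi] %*% A0inv
  Sigma <- A0 %*% t(A0)
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(psi = psi, H = H, Sigma = Sigma, A0 = A0,
                 freqs = S$freqs, fs = S$fs,
                 residual = res$residual, iterations = res$iterations,
                 converged = res$converged, M = M),
            class = "spectral_factorization")
}

#' @export
print.spectral_factorization <- function(x, ...) {
  cat(sprintf(
    "spectral_factorization: %d channels, %d frequencies; %d iterations, %s (residual %.3g)\n",
    x$M, length(x$freqs), x$iterations,
    if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}
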