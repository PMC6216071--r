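# Oracles and fixture builders shared across the suite.  Everything here is
# independent of the code paths it checks: autocovariances come from the
# companion-form Lyapunov equation, spectra from direct transfer-function
# algebra, and parametric fits from stats::ar.ols.

# theoretical autocovariance sequence Gamma(0..max_lag) of a stable MVAR
# model, via the companion-form discrete Lyapunov equation solved by
# vectorization
mvar_autocov_oracle <- function(model, max_lag) {
  M <- model$M; p <- max(model$p, 1L)
  A <- matrix(0, p * M, p * M)
  for (k in seq_len(model$p))
    A[1:M, ((k - 1) * M + 1):(k * M)] <- model$A[, , k]
  if (p > 1) A[(M + 1):(p * M), 1:((p - 1) * M)] <- diag((p - 1) * M)
  Q <- matrix(0, p * M, p * M)
  Q[1:M, 1:M] <- model$Sigma
  n <- p * M
  G <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Q)), n, n)
  out <- vector("list", max_lag + 1)
  out[[1]] <- G[1:M, 1:M]
  Gl <- G
  for (l in seq_len(max_lag)) {
    Gl <- A %*% Gl
    out[[l + 1]] <- Gl[1:M, 1:M]
  }
  out
}

# Geweke's pairwise measure evaluated directly from the true transfer
# function and innovation covariance of a 2-channel model (no factorization,
# no estimation) -- the parametric oracle for the nonparametric chain
geweke_pairwise_oracle <- function(model, freqs) {
  stopifnot(model$M == 2)
  Sg <- model$Sigma
  out <- array(0, dim = c(2, 2, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(2) * (1 + 0i)
    for (k in seq_len(model$p))
      Af <- Af - model$A[, , k] * exp(-2i * pi * freqs[fi] * k / model$fs)
    H <- solve(Af)
    Sp <- Re(diag(H %*% Sg %*% Conj(t(H))))
    for (i in 1:2) {
      j <- 3 - i
      den <- Sp[i] - (Sg[j, j] - Sg[i, j]^2 / Sg[i, i]) * Mod(H[i, j])^2
      out[i, j, fi] <- log(Sp[i] / den)
    }
  }
  out
}

# random stable 2-channel MVAR(2) models for property loops
random_stable_model2 <- function(seed) {
  set.seed(seed)
  repeat {
    A1 <- matrix(rnorm(4, sd = 0.4), 2, 2)
    A2 <- matrix(rnorm(4, sd = 0.25), 2, 2)
    L <- matrix(rnorm(4, sd = 0.3), 2, 2)
    Sg <- diag(2) + 0.3 * (L + t(L)) / 2
    m <- tryCatch(mvar_model(list(A1, A2), sigma = Sg, fs = 200),
                  error = function(e) NULL)
    if (!is.null(m) && companion_spectral_radius(m) < 0.95) return(m)
  }
}

# frozen reference values for the Slepian tapers (n = 64, NW = 4, 7 tapers),
# computed with an independent implementation of the same definition
dpss_reference_64_4 <- data.frame(
  i = c(1L, 32L, 64L, 1L, 21L, 11L, 41L, 6L),
  k = c(1L, 1L, 1L, 2L, 2L, 4L, 5L, 7L),
  value = c(0.000031063683, 0.247337186560, 0.000031063683,
            0.000247111460, 0.203752502989, 0.180218241879,
            -0.129316118833, 0.219221808860))

expect_ggc_shape <- function(g, M, testing = "none") {
  expect_s3_class(g, "ggc")
  expect_equal(dim(g$values)[1:2], c(M, M))
  expect_identical(g$testing, testing)
  expect_true(all(diag(apply(g$values, c(1, 2), max)) == 0))
}
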