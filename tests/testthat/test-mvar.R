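# MVAR model construction, simulation and analytic spectra.

test_that("two-node oscillator builder reproduces the design coefficients", {
  m <- two_node_oscillator()
  expect_equal(m$M, 2)
  expect_equal(m$p, 2)
  # self terms 2 r cos(theta) and -r^2 with r = 0.8, f = 40 Hz at 200 Hz
  expect_equal(m$A[1, 1, 1], 2 * 0.8 * cos(0.4 * pi), tolerance = 1e-12)
  expect_equal(m$A[1, 1, 2], -0.64, tolerance = 1e-12)
  # default coupling 1 -> 2 at lags 1 and 2
  expect_equal(m$A[2, 1, 1], -0.35)
  expect_equal(m$A[2, 1, 2], 0.7)
  expect_equal(m$A[1, 2, 1], 0)
  expect_identical(m$Sigma, diag(2))
  expect_lt(companion_spectral_radius(m), 1)
})

test_that("snr network builder reproduces the broadband AR(2) benchmark", {
  m <- snr_network(2, list(c(1, 2)))
  expect_equal(m$A[, , 1], matrix(c(0.5, 0.2, 0, 0.5), 2, 2))
  expect_equal(m$A[, , 2], matrix(c(-0.8, -0.1, 0, -0.8), 2, 2))
  # no interactions: three independent nodes, zero cross terms
  m3 <- snr_network(3, list())
  expect_true(all(m3$A[, , 1][lower.tri(m3$A[, , 1])] == 0))
  expect_error(snr_network(3, list(c(1, 4))), "outside")
  expect_error(snr_network(3, list(c(1, 2), c(3, 2))), "at most one source")
  expect_error(snr_network(3, list(c(2, 2))), "differ")
})

test_that("unstable or invalid models are rejected with informative errors", {
  expect_error(mvar_model(list(matrix(1.01, 1, 1))), "spectral radius")
  expect_error(two_node_oscillator(r1 = 1.2), "pole radii")
  expect_error(mvar_model(list(matrix(0.5, 1, 1)), sigma = matrix(-1, 1, 1)),
               "positive definite")
  expect_error(mvar_model(list(matrix(NA_real_, 1, 1))), "finite")
})

test_that("analytic spectrum peaks at the AR(2) closed-form frequency", {
  # decoupled oscillators: cross-spectrum identically zero, peak at the
  # closed-form argmax cos(w) = -a1 (1 - a2) / (4 a2)
  m <- two_node_oscillator(coupling = c(0, 0))
  S <- analytic_spectrum(m, freqs = seq(0, 100, by = 0.05))
  expect_lt(max(Mod(S$S[1, 2, ])), 1e-14)
  a <- c(m$A[1, 1, 1], m$A[1, 1, 2])
  f_closed <- ar2_peak_freq(a[1], a[2], m$fs)
  expect_equal(f_closed, 39.74, tolerance = 0.01)
  expect_equal(S$freqs[which.max(Re(S$S[1, 1, ]))], f_closed,
               tolerance = 0.002)
})

test_that("white-noise model yields a flat diagonal spectrum", {
  m <- mvar_model(array(0, c(2, 2, 0)), sigma = diag(c(1, 2)), fs = 100)
  S <- analytic_spectrum(m, n_samples = 64)
  inner <- 2:(length(S$freqs) - 1)
  expect_equal(Re(S$S[1, 1, inner]), rep(2 / 100, length(inner)),
               tolerance = 1e-12)
  expect_equal(Re(S$S[2, 2, inner]) / Re(S$S[1, 1, inner]),
               rep(2, length(inner)), tolerance = 1e-12)
  expect_lt(max(Mod(S$S[1, 2, ])), 1e-14)
})

test_that("analytic spectrum integrates to the process variance", {
  m <- two_node_oscillator()
  S <- analytic_spectrum(m, n_samples = 2048)
  gam0 <- mvar_autocov_oracle(m, 0)[[1]]
  df <- S$freqs[2] - S$freqs[1]
  for (ch in 1:2) {
    psd <- Re(S$S[ch, ch, ])
    integral <- df * (sum(psd) - (psd[1] + psd[length(psd)]) / 2)
    expect_equal(integral, gam0[ch, ch], tolerance = 0.01 * gam0[ch, ch])
  }
})

test_that("simulation is seed-deterministic with counter-based trial streams", {
  m <- two_node_oscillator()
  x1 <- simulate(m, nsim = 5, seed = 7, n_samples = 100)
  x2 <- simulate(m, nsim = 5, seed = 7, n_samples = 100)
  expect_identical(x1$data, x2$data)
  # growing the trial count must not reshuffle earlier trials
  x8 <- simulate(m, nsim = 8, seed = 7, n_samples = 100)
  expect_identical(x8$data[, , 1:5], x1$data)
  x3 <- simulate(m, nsim = 5, seed = 8, n_samples = 100)
  expect_false(identical(x3$data, x1$data))
})

test_that("simulated moments match closed forms and the Yule-Walker oracle", {
  # univariate AR(1), a = 0.5: stationary variance 1 / (1 - 0.25)
  m1 <- mvar_model(list(matrix(0.5, 1, 1)), fs = 1)
  x <- simulate(m1, nsim = 10, seed = 1, n_samples = 10000)
  expect_equal(var(as.vector(x$data)), 1 / 0.75, tolerance = 0.05)
  # order-0 model: sample covariance of pooled output equals Sigma
  Sg <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  m0 <- mvar_model(array(0, c(2, 2, 0)), sigma = Sg, fs = 1)
  x0 <- simulate(m0, nsim = 20, seed = 2, n_samples = 2500, burn_in = 0)
  pooled <- matrix(aperm(x0$data, c(1, 3, 2)), ncol = 2)
  expect_equal(cov(pooled), Sg, tolerance = 0.05)
  # full MVAR: pooled sample autocovariance at lags 0..p vs Lyapunov oracle
  m <- two_node_oscillator()
  xs <- simulate(m, nsim = 250, seed = 3, n_samples = 400)
  G <- mvar_autocov_oracle(m, m$p)
  d <- dim(xs$data)
  for (lag in 0:m$p) {
    emp <- matrix(0, 2, 2)
    for (k in seq_len(d[3])) {
      a <- xs$data[(1 + lag):d[1], , k]
      b <- xs$data[1:(d[1] - lag), , k]
      emp <- emp + crossprod(a, b) / (d[1] - lag)
    }
    emp <- emp / d[3]
    expect_equal(emp, G[[lag + 1]], tolerance = 0.05 * max(abs(G[[1]])))
  }
})

test_that("simulation refuses unstable models and bad arguments", {
  m <- two_node_oscillator()
  expect_error(simulate(m, nsim = 0, seed = 1), "positive integer")
  expect_error(simulate(m, nsim = 2, seed = 1, n_samples = 1), "model order")
})

test_that("models round-trip through the JSON config format", {
  m <- snr_network(3, list(c(1, 2), c(2, 3)))
  path <- tempfile(fileext = ".json")
  write_mvar_json(m, path)
  m2 <- read_mvar_json(path)
  expect_equal(m2$A, m$A)
  expect_equal(m2$Sigma, m$Sigma)
  expect_equal(m2$fs, m$fs)
})
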