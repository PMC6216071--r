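# Observation-corruption models: common reference, additive noise, mixing.

test_that("reference signals have the requested spectral character", {
  # oscillatory reference at 20 Hz: periodogram peak near the closed-form
  # AR(2) maximum (18.9 Hz for r = 0.8 at 200 Hz)
  R <- make_reference("ar2", n_samples = 4000, n_trials = 4, fs = 200,
                      r_R = 0.8, f_R = 20, seed = 5)
  sp <- spec.pgram(R$data[, 1], taper = 0.1, spans = 31, plot = FALSE)
  pk <- sp$freq[which.max(sp$spec)] * 200
  expect_equal(pk, ar2_peak_freq(2 * 0.8 * cos(2 * pi * 20 / 200), -0.64, 200),
               tolerance = 2)
  # 70 Hz design: closed-form peak 70.58 Hz
  expect_equal(ar2_peak_freq(2 * 0.8 * cos(2 * pi * 70 / 200), -0.64, 200),
               70.58, tolerance = 0.01)
  # white reference: unit variance, no detectable autocorrelation
  Rw <- make_reference("white", n_samples = 20000, n_trials = 1, fs = 200,
                       variance = 1, seed = 6)
  expect_equal(var(Rw$data[, 1]), 1, tolerance = 0.05)
  bt <- Box.test(Rw$data[, 1], lag = 20, type = "Ljung-Box")
  expect_gt(bt$p.value, 0.01)
  expect_error(make_reference("triangle", 10, 1, 200), "arg")
})

test_that("common-reference corruption follows the stated mixing algebra", {
  m <- two_node_oscillator()
  x <- simulate(m, nsim = 6, seed = 1, n_samples = 200)
  R <- make_reference("white", 200, 6, fs = 200, seed = 2)
  # alpha = 0 is the identity
  expect_identical(apply_common_reference(x, R, 0)$data, x$data)
  # the same R is subtracted from both channels: channel difference of the
  # corrupted data equals (1 - alpha) times the clean difference
  xc <- apply_common_reference(x, R, 0.3)
  expect_equal(xc$data[, 1, ] - xc$data[, 2, ],
               0.7 * (x$data[, 1, ] - x$data[, 2, ]), tolerance = 1e-12)
  # explicit formula on one sample
  expect_equal(xc$data[5, 1, 2], 0.7 * x$data[5, 1, 2] - 0.3 * R$data[5, 2])
  # variance algebra: independent X (var v) and R (var u) at alpha = 0.5
  set.seed(3)
  v <- 2.3; u <- 1.4
  xa <- trials_array(array(rnorm(5e4 * 2, sd = sqrt(v)), c(5e4, 2, 1)),
                     fs = 100)
  Ra <- make_reference("white", 5e4, 1, fs = 100, variance = u, seed = 9)
  xca <- apply_common_reference(xa, Ra, 0.5)
  expect_equal(var(xca$data[, 1, 1]), 0.25 * (v + u), tolerance = 0.03)
  expect_error(apply_common_reference(x, R, 1.2), "0, 1")
  Rshort <- make_reference("white", 100, 6, fs = 200, seed = 2)
  expect_error(apply_common_reference(x, Rshort, 0.5), "dimensions")
})

test_that("noise ensembles honor mixing mode, color and rank constraints", {
  # identity mixing: mixed noise equals the sources exactly
  E <- make_noise_ensemble(3, 3, color = "white", K_mode = "identity",
                           n_samples = 100, n_trials = 2, fs = 200, seed = 1)
  expect_identical(E$data, E$sources)
  expect_error(make_noise_ensemble(3, 2, K_mode = "identity",
                                   n_samples = 10, n_trials = 1, fs = 200),
               "S_count = M")
  # random full-rank K: unit-norm rows, rank M
  Em <- make_noise_ensemble(3, 3, color = "white",
                            K_mode = "random_full_rank",
                            n_samples = 50, n_trials = 1, fs = 200, seed = 2)
  expect_equal(rowSums(Em$K^2), rep(1, 3), tolerance = 1e-12)
  expect_equal(qr(Em$K)$rank, 3)
  expect_error(make_noise_ensemble(2, 2, K_mode = "given",
                                   K = matrix(1, 2, 2),
                                   n_samples = 10, n_trials = 1, fs = 200),
               "rank deficient")
  # pink sources: log-log periodogram slope close to -1
  Ep <- make_noise_ensemble(1, 1, color = "pink", K_mode = "identity",
                            n_samples = 2^14, n_trials = 1, fs = 200,
                            seed = 3)
  sp <- spec.pgram(Ep$sources[, 1, 1], plot = FALSE)
  keep <- sp$freq > 1 / 200 & sp$freq <= 0.5
  fit <- lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.2)
  # mixture: odd sources white (flat), even pink (sloped)
  Ew <- make_noise_ensemble(2, 2, color = "white+pink", K_mode = "identity",
                            n_samples = 2^13, n_trials = 1, fs = 200,
                            seed = 4)
  slope <- function(v) {
    sp <- spec.pgram(v, plot = FALSE)
    keep <- sp$freq > 1 / 200 & sp$freq <= 0.5
    unname(coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  }
  expect_equal(slope(Ew$sources[, 1, 1]), 0, tolerance = 0.2)
  expect_equal(slope(Ew$sources[, 2, 1]), -1, tolerance = 0.25)
})

test_that("additive noise corrupts only the selected channels", {
  m <- snr_network(2, list(c(1, 2)))
  x <- simulate(m, nsim = 4, seed = 1, n_samples = 150)
  E <- make_noise_ensemble(2, 2, K_mode = "identity", n_samples = 150,
                           n_trials = 4, fs = 200, seed = 2)
  xc <- apply_additive_noise(x, E, 0.4, channels = 1)
  # the noise-free channel is copied bit-identically
  expect_identical(xc$data[, 2, ], x$data[, 2, ])
  expect_equal(xc$data[, 1, ], 0.6 * x$data[, 1, ] + 0.4 * E$data[, 1, ])
  expect_identical(apply_additive_noise(x, E, 0)$data, x$data)
  expect_error(apply_additive_noise(x, E, -0.1), "0, 1")
  expect_error(apply_additive_noise(x, E, 0.5, channels = 5), "subset")
  # variance algebra at alpha = 0.3: 0.49 v + 0.09 u
  set.seed(5)
  v <- 1.7; u <- 2.2
  xa <- trials_array(array(rnorm(4e4, sd = sqrt(v)), c(4e4, 1, 1)), fs = 100)
  Ea <- make_noise_ensemble(1, 1, K_mode = "identity", n_samples = 4e4,
                            n_trials = 1, fs = 100, seed = 11)
  Ea$data <- Ea$data * sqrt(u); Ea$sources <- Ea$sources * sqrt(u)
  xca <- apply_additive_noise(xa, Ea, 0.3)
  expect_equal(var(xca$data[, 1, 1]), 0.49 * v + 0.09 * u, tolerance = 0.05)
})

test_that("corruption streams are independent of the node innovations", {
  m <- two_node_oscillator()
  x <- simulate(m, nsim = 1, seed = 77, n_samples = 20000)
  R <- make_reference("white", 20000, 1, fs = 200, seed = 77)
  E <- make_noise_ensemble(2, 2, K_mode = "identity", n_samples = 20000,
                           n_trials = 1, fs = 200, seed = 77)
  # same master seed, distinct streams: lag-0 cross-correlation near zero
  expect_lt(abs(cor(x$data[, 1, 1], R$data[, 1])), 0.03)
  expect_lt(abs(cor(x$data[, 1, 1], E$data[, 1, 1])), 0.03)
  expect_lt(abs(cor(R$data[, 1], E$data[, 1, 1])), 0.03)
})

test_that("corruptions are exactly invertible when the weights are known", {
  m <- two_node_oscillator()
  x <- simulate(m, nsim = 3, seed = 1, n_samples = 100)
  R <- make_reference("ar2", 100, 3, fs = 200, seed = 2)
  a <- 0.45
  xc <- apply_common_reference(x, R, a)
  d <- dim(x$data)
  Rexp <- aperm(array(R$data, c(d[1], d[3], d[2])), c(1, 3, 2))
  rec <- (xc$data + a * Rexp) / (1 - a)
  expect_equal(rec, x$data, tolerance = 1e-12)
})
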