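# Scenario drivers: sweep a corruption weight over a grid, estimate plain GGC
# and tr-GGC per grid point over independent replicates, and summarize each
# edge by median and 5th/95th percentile curves.

# run one (data -> ggc + tr_ggc) estimation, collecting non-convergence
# warnings instead of printing them
estimate_both <- function(X, nw, conditional) {
  nonconv <- 0L
  h <- function(w) {
    if (grepl("did not converge", conditionMessage(w))) {
      nonconv <<- nonconv + 1L
      invokeRestart("muffleWarning")
    }
  }
  est <- if (conditional) conditional_ggc else pairwise_ggc
  g <- withCallingHandlers(est(X, nw = nw), warning = h)
  tg <- withCallingHandlers(tr_ggc(X, nw = nw, conditional = conditional),
                            warning = h)
  list(ggc = g, tr = tg, nonconverged = nonconv)
}

summarize_sweep <- function(store, alpha_grid, freqs, M) {
  # store: list over alpha of list(ggc = M x M x F x R, tr = ...)
  rows <- list()
  for (ai in seq_along(alpha_grid)) {
    for (mode in c("ggc", "tr_ggc")) {
      arr <- store[[ai]][[if (mode == "ggc") "ggc" else "tr"]]
      med <- apply(arr, c(1, 2, 3), median)
      q05 <- apply(arr, c(1, 2, 3), quantile, probs = 0.05, names = FALSE)
      q95 <- apply(arr, c(1, 2, 3), quantile, probs = 0.95, names = FALSE)
      for (i in seq_len(M)) for (j in seq_len(M)) {
        if (i == j) next
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = alpha_grid[ai], mode = mode, receiver = i, sender = j,
          frequency = freqs, median = med[i, j, ], q05 = q05[i, j, ],
          q95 = q95[i, j, ])
      }
    }
  }
  do.call(rbind, rows)
}

new_ggc_sweep <- function(summary, alpha_grid, freqs, config, diagnostics) {
  structure(list(summary = summary, alpha_grid = alpha_grid, freqs = freqs,
                 config = config, diagnostics = diagnostics),
            class = "ggc_sweep")
}

#' @export
print.ggc_sweep <- function(x, ...) {
  cat(sprintf("ggc_sweep: %s; %d grid points (alpha %g-%g), %d repeats\n",
              x$config$scenario, length(x$alpha_grid), min(x$alpha_grid),
              max(x$alpha_grid), x$config$n_repeats))
  nc <- sum(x$diagnostics$nonconverged)
  cat(sprintf("  factorization non-convergence events: %d\n", nc))
  invisible(x)
}

#' @export
as.data.frame.ggc_sweep <- function(x, ...) x$summary

#' Extract one summarized influence curve from a sweep
#'
#' @param x a `"ggc_sweep"`.
#' @param alpha grid point.
#' @param mode `"ggc"` or `"tr_ggc"`.
#' @param receiver,sender channel indices (influence sender -> receiver).
#' @return data.frame with `frequency`, `median`, `q05`, `q95`.
#' @export
sweep_curve <- function(x, alpha, mode, receiver, sender) {
  stopifnot(inherits(x, "ggc_sweep"))
  s <- x$summary
  out <- s[abs(s$alpha - alpha) < 1e-9 & s$mode == mode &
             s$receiver == receiver & s$sender == sender, ]
  if (nrow(out) == 0) stop_trggc("no such grid point / edge in the sweep")
  out[order(out$frequency), c("frequency", "median", "q05", "q95")]
}

#' Band-mean of the median influence curve, per grid point
#'
#' @inheritParams sweep_curve
#' @param band length-2 band limits (Hz).
#' @return named vector over the alpha grid of band means of the median curve.
#' @export
sweep_band_mean <- function(x, mode, receiver, sender, band) {
  vapply(x$alpha_grid, function(a) {
    cv <- sweep_curve(x, a, mode, receiver, sender)
    mean(cv$median[cv$frequency >= band[1] & cv$frequency <= band[2]])
  }, numeric(1)) |> stats::setNames(x$alpha_grid)
}

#' Plot a sweep summary
#'
#' Median curves (solid) with 5th-95th percentile shading for one edge and
#' mode, one curve per grid point.
#'
#' @param x a `"ggc_sweep"`.
#' @param mode `"ggc"` or `"tr_ggc"`.
#' @param receiver,sender edge to display.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ggc_sweep <- function(x, mode = "ggc", receiver = 2, sender = 1, ...) {
  cols <- grDevices::hcl.colors(length(x$alpha_grid), "Zissou 1")
  first <- TRUE
  for (ai in seq_along(x$alpha_grid)) {
    cv <- sweep_curve(x, x$alpha_grid[ai], mode, receiver, sender)
    if (first) {
      matplot(cv$frequency, cv$median, type = "l", lty = 1, col = cols[ai],
              xlab = "frequency (Hz)", ylab = mode,
              main = sprintf("%d ← %d", receiver, sender),
              ylim = c(0, max(x$summary$q95[x$summary$mode == mode &
                x$summary$receiver == receiver &
                x$summary$sender == sender])), ...)
      first <- FALSE
    } else lines(cv$frequency, cv$median, col = cols[ai])
  }
  legend("topright", legend = x$alpha_grid, col = cols, lty = 1, cex = 0.6,
         title = "alpha")
  invisible(x)
}

#' Common-reference corruption sweep
#'
#' Reproduces the common-reference experiment: the two-node 40 Hz oscillator
#' network ([two_node_oscillator()], node 1 driving node 2) is simulated with
#' `n_trials` trials of `n_samples` samples, a shared reference signal is
#' built per `ref_type` (white noise with the innovation variance, or a
#' damped oscillator at 40, 20 or 70 Hz with pole radius 0.8), and for every
#' weight in `alpha_grid` the reference-corrupted observations
#' `x' = (1 - alpha) x - alpha R` are analyzed with plain GGC and tr-GGC.
#' The whole estimation is repeated over `n_repeats` independent replicates
#' and summarized by median and 5th/95th percentile curves per edge.
#'
#' @param ref_type `"white"`, `"osc_same_40"`, `"osc_20"` or `"osc_70"`.
#' @param alpha_grid weights in `[0, 1]`; default `seq(0.1, 0.9, by = 0.1)`.
#' @param n_trials trials per replicate; default 100.
#' @param n_samples samples per trial; default 400 (2 s at 200 Hz).
#' @param n_repeats independent replicates; default 10.
#' @param nw multitaper time-bandwidth; default 4.
#' @param seed master seed.
#' @return a `"ggc_sweep"` object.
#' @export
run_common_reference <- function(ref_type = c("white", "osc_same_40",
                                              "osc_20", "osc_70"),
                                 alpha_grid = seq(0.1, 0.9, by = 0.1),
                                 n_trials = 100, n_samples = 400,
                                 n_repeats = 10, nw = 4, seed = 1) {
  ref_type <- match.arg(ref_type)
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop_trggc("'alpha_grid' must lie in [0, 1]")
  model <- two_node_oscillator()
  fs <- model$fs
  nf <- floor(n_samples / 2) + 1L
  freqs <- (0:(nf - 1)) * fs / n_samples
  store <- lapply(seq_along(alpha_grid), function(i)
    list(ggc = array(0, c(2, 2, nf, n_repeats)),
         tr = array(0, c(2, 2, nf, n_repeats))))
  diag_rows <- list()
  for (r in seq_len(n_repeats)) {
    rseed <- substream_seed(seed, "scenario", r)
    x <- simulate(model, nsim = n_trials, seed = rseed,
                  n_samples = n_samples)
    R <- switch(ref_type,
      white = make_reference("white", n_samples, n_trials, fs,
                             variance = 1, seed = rseed),
      osc_same_40 = make_reference("ar2", n_samples, n_trials, fs,
                                   r_R = 0.8, f_R = 40, seed = rseed),
      osc_20 = make_reference("ar2", n_samples, n_trials, fs,
                              r_R = 0.8, f_R = 20, seed = rseed),
      osc_70 = make_reference("ar2", n_samples, n_trials, fs,
                              r_R = 0.8, f_R = 70, seed = rseed))
    for (ai in seq_along(alpha_grid)) {
      xc <- apply_common_reference(x, R, alpha_grid[ai])
      eb <- estimate_both(xc, nw, conditional = FALSE)
      store[[ai]]$ggc[, , , r] <- eb$ggc$values
      store[[ai]]$tr[, , , r] <- eb$tr$values
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        alpha = alpha_grid[ai], repeat_id = r, nonconverged = eb$nonconverged)
    }
  }
  cfg <- list(scenario = paste0("common_reference/", ref_type),
              ref_type = ref_type, model = "two_node_oscillator defaults",
              n_trials = n_trials, n_samples = n_samples, fs = fs, nw = nw,
              n_repeats = n_repeats, seed = seed)
  new_ggc_sweep(summarize_sweep(store, alpha_grid, freqs, 2), alpha_grid,
                freqs, cfg, do.call(rbind, diag_rows))
}

#' Additive-noise / SNR-imbalance sweep
#'
#' Reproduces the additive-noise experiments: the broadband AR(2) network
#' ([snr_network()]) with the requested interactions is simulated, a noise
#' ensemble is built (`mode = "IND"`: independent sources, identity mixing;
#' `mode = "MIX"`: sources mixed through a random full-rank matrix), and for
#' every weight in `alpha_grid` the noise is superimposed on
#' `noisy_channels` via `x' = (1 - alpha) x + alpha e`.  Plain GGC and
#' tr-GGC (pairwise or conditional per `conditional`) are estimated per grid
#' point and summarized over `n_repeats` replicates.
#'
#' With `M = 2`, `interactions = list(c(1, 2))` and `noisy_channels = 1`
#' this is the bivariate SNR-imbalance experiment (additive noise on the
#' driver only, receiver noise-free).
#'
#' @param mode `"IND"` or `"MIX"`.
#' @param M number of channels; default 2.
#' @param interactions list of `c(source, target)` pairs; default
#'   `list(c(1, 2))`.
#' @param noisy_channels channels receiving additive noise; default 1.
#' @param noise_color `"white"` or `"white+pink"`.
#' @param conditional use conditional (TRUE) or pairwise (FALSE) GGC.
#' @inheritParams run_common_reference
#' @return a `"ggc_sweep"` object.
#' @export
run_additive_noise <- function(mode = c("IND", "MIX"), M = 2,
                               interactions = list(c(1, 2)),
                               noisy_channels = 1,
                               noise_color = c("white", "white+pink", "pink"),
                               conditional = FALSE,
                               alpha_grid = seq(0.1, 0.9, by = 0.1),
                               n_trials = 100, n_samples = 400,
                               n_repeats = 10, nw = 4, seed = 1) {
  mode <- match.arg(mode)
  noise_color <- match.arg(noise_color)
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop_trggc("'alpha_grid' must lie in [0, 1]")
  model <- snr_network(M, interactions)
  fs <- model$fs
  nf <- floor(n_samples / 2) + 1L
  freqs <- (0:(nf - 1)) * fs / n_samples
  store <- lapply(seq_along(alpha_grid), function(i)
    list(ggc = array(0, c(M, M, nf, n_repeats)),
         tr = array(0, c(M, M, nf, n_repeats))))
  diag_rows <- list()
  for (r in seq_len(n_repeats)) {
    rseed <- substream_seed(seed, "scenario", r)
    x <- simulate(model, nsim = n_trials, seed = rseed,
                  n_samples = n_samples)
    E <- make_noise_ensemble(
      M, S_count = M, color = noise_color,
      K_mode = if (mode == "IND") "identity" else "random_full_rank",
      n_samples = n_samples, n_trials = n_trials, fs = fs, seed = rseed)
    for (ai in seq_along(alpha_grid)) {
      xc <- apply_additive_noise(x, E, alpha_grid[ai],
                                 channels = noisy_channels)
      eb <- estimate_both(xc, nw, conditional = conditional)
      store[[ai]]$ggc[, , , r] <- eb$ggc$values
      store[[ai]]$tr[, , , r] <- eb$tr$values
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        alpha = alpha_grid[ai], repeat_id = r, nonconverged = eb$nonconverged)
    }
  }
  cfg <- list(scenario = paste0("additive_noise/", mode),
              mode = mode, M = M, interactions = interactions,
              noisy_channels = noisy_channels, noise_color = noise_color,
              conditional = conditional, n_trials = n_trials,
              n_samples = n_samples, fs = fs, nw = nw,
              n_repeats = n_repeats, seed = seed)
  new_ggc_sweep(summarize_sweep(store, alpha_grid, freqs, M), alpha_grid,
                freqs, cfg, do.call(rbind, diag_rows))
}

#' Load and validate the three-node MVAR(3) demonstration model
#'
#' Reads the coefficient configuration of the three-node MVAR(3) network of
#' Stokes & Purdon's conditional-causality demonstration (node 1 drives
#' node 2, node 2 drives node 3; the nodes resonate at 40, 10 and 50 Hz at a
#' 120 Hz sampling rate) and validates stability and the three pole
#' frequencies before returning it as an [mvar_model()].
#'
#' @param path config file (JSON); default the copy shipped with the package.
#' @return an [mvar_model()].
#' @export
load_stokes_purdon_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stokes_purdon_mvar3.json",
                                package = "trggc")
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop_trggc(
      "MVAR(3) coefficient config not found; the model is defined in the ",
      "original three-node conditional-causality example of Stokes & Purdon ",
      "(transcribe it into a JSON file readable by read_mvar_json, with an ",
      "'expected_resonances_hz' field)")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- read_mvar_json(path)
  expect <- obj$expected_resonances_hz
  if (!is.null(expect)) {
    for (i in seq_len(model$M)) {
      a1 <- model$A[i, i, 1]; a2 <- model$A[i, i, 2]
      r <- sqrt(-a2)
      fpole <- acos(a1 / (2 * r)) * model$fs / (2 * pi)
      if (abs(fpole - expect[i]) > 0.1)
        stop_trggc(sprintf(
          "node %d pole frequency %.2f Hz does not match expected %.2f Hz",
          i, fpole, expect[i]))
    }
  }
  model
}

#' Conditional-causality demonstration on the three-node MVAR(3) network
#'
#' Simulates independent realizations of the Stokes-Purdon three-node MVAR(3)
#' network, estimates conditional GGC nonparametrically per realization, and
#' summarizes the estimates by median and 5th/95th percentile curves per
#' edge.  Also returns a pooled estimate using all realizations together as
#' trials, the true influence curves computed from the analytic spectrum of
#' the generating model, and the per-node pooled multitaper PSDs.
#'
#' @param n_realizations number of independent realizations; default 1000.
#' @param n_samples samples per realization; default 500.
#' @param nw multitaper time-bandwidth; default 4.
#' @param seed master seed.
#' @param model_config path to the coefficient config
#'   (see [load_stokes_purdon_model()]).
#' @return object of class `"stokes_purdon_result"`: `freqs`, `median`,
#'   `q05`, `q95` (`3 x 3 x F` arrays over realizations), `pooled` and
#'   `true` (`"ggc"` objects), `psd` (`3 x F`), `psd_peak_hz`, `config`.
#' @export
run_stokes_purdon <- function(n_realizations = 1000, n_samples = 500,
                              nw = 4, seed = 1, model_config = NULL) {
  model <- load_stokes_purdon_model(model_config)
  M <- model$M
  x <- simulate(model, nsim = n_realizations, seed = seed,
                n_samples = n_samples)
  nf <- floor(n_samples / 2) + 1L
  vals <- array(0, c(M, M, nf, n_realizations))
  nonconv <- 0L
  h <- function(w) {
    if (grepl("did not converge", conditionMessage(w))) {
      nonconv <<- nonconv + 1L
      invokeRestart("muffleWarning")
    }
  }
  for (k in seq_len(n_realizations)) {
    xk <- trials_array(x$data[, , k, drop = FALSE], fs = model$fs)
    g <- withCallingHandlers(conditional_ggc(xk, nw = nw), warning = h)
    vals[, , , k] <- g$values
  }
  pooled <- withCallingHandlers(conditional_ggc(x, nw = nw), warning = h)
  Strue <- analytic_spectrum(model, freqs = pooled$freqs)
  true <- conditional_ggc(Strue, tol = 1e-12, max_iter = 200)
  Spool <- multitaper_csd(x, nw = nw)
  psd <- t(vapply(seq_len(M), function(i) Re(Spool$S[i, i, ]),
                  numeric(nf)))
  peaks <- Spool$freqs[apply(psd, 1, which.max)]
  structure(list(
    freqs = pooled$freqs,
    median = apply(vals, c(1, 2, 3), median),
    q05 = apply(vals, c(1, 2, 3), quantile, probs = 0.05, names = FALSE),
    q95 = apply(vals, c(1, 2, 3), quantile, probs = 0.95, names = FALSE),
    pooled = pooled, true = true, psd = psd, psd_peak_hz = peaks,
    config = list(n_realizations = n_realizations, n_samples = n_samples,
                  fs = model$fs, nw = nw, seed = seed,
                  nonconverged = nonconv)),
    class = "stokes_purdon_result")
}

#' @export
print.stokes_purdon_result <- function(x, ...) {
  cat(sprintf(
    "stokes_purdon_result: %d realizations x %d samples at %g Hz (NW = %g)\n",
    x$config$n_realizations, x$config$n_samples, x$config$fs, x$config$nw))
  cat("  node PSD peaks (Hz):", paste(round(x$psd_peak_hz, 1),
                                      collapse = ", "), "\n")
  bm <- apply(x$pooled$values, c(1, 2), mean)
  cat("  pooled mean conditional GGC (receiver row <- sender column):\n")
  print(round(bm, 4))
  invisible(x)
}
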