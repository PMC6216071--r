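# Internal helpers shared across modules.

# Deterministic substream seeds: every stochastic primitive draws from its own
# stream derived from (master seed, stream id, counter).  Trial k of a
# simulation always gets the same innovations whatever the total trial count,
# and reference/noise streams never collide with node innovations.
.stream_ids <- c(innovations = 1L, reference = 2L, noise_sources = 3L,
                 mixing = 4L, sep = 5L, scenario = 6L)

substream_seed <- function(master, stream, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  sid <- if (is.character(stream)) .stream_ids[[stream]] else as.integer(stream)
  m <- 2147483647                       # 2^31 - 1
  s <- (abs(master) %% m + 999983 * sid + 9973 * (counter %% 100000)) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

stop_trggc <- function(...) stop(..., call. = FALSE)

# closed-form frequency of the AR(2) spectral peak for coefficients
# (a1, a2) in x(t) = a1 x(t-1) + a2 x(t-2) + w(t); NA when no interior peak
ar2_peak_freq <- function(a1, a2, fs) {
  cw <- -a1 * (1 - a2) / (4 * a2)
  if (!is.finite(cw) || abs(cw) > 1) return(NA_real_)
  acos(cw) * fs / (2 * pi)
}
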