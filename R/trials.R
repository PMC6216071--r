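#' Trial-based multichannel signal container
#'
#' The universal signal container of the package: a real array with time on
#' the first dimension, channels on the second and trials on the third, plus
#' the sampling rate and an optional time axis.
#'
#' @param data numeric array `time x channel x trial` (a `time x channel`
#'   matrix is promoted to one trial).
#' @param fs sampling rate in Hz.
#' @param times optional time axis, one value per sample.
#' @param time_unit unit of `times` (`"s"` or `"ms"`).
#' @return object of class `"trials_array"` with elements `data`, `fs`,
#'   `times`, `time_unit`.
#' @examples
#' x <- trials_array(array(rnorm(40), c(10, 2, 2)), fs = 10)
#' dim(x$data)
#' @export
trials_array <- function(data, fs, times = NULL, time_unit = "s") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_trggc("'data' must be a time x channel x trial array")
  if (!all(is.finite(data))) stop_trggc("'data' must be finite")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0))
    stop_trggc("'fs' must be a positive sampling rate in Hz")
  if (!is.null(times) && length(times) != dim(data)[1])
    stop_trggc("'times' length must equal the number of samples")
  structure(list(data = data, fs = fs, times = times, time_unit = time_unit),
            class = "trials_array")
}

#' @export
print.trials_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trials_array: %d samples x %d channels x %d trials, Fs = %g Hz\n",
              d[1], d[2], d[3], x$fs))
  if (!is.null(x$times))
    cat(sprintf("  time axis: %g to %g %s\n", x$times[1], x$times[length(x$times)],
                x$time_unit))
  invisible(x)
}

n_channels <- function(x) dim(x$data)[2]
n_trials <- function(x) dim(x$data)[3]
n_samples_of <- function(x) dim(x$data)[1]

#' Time-reverse every trial
#'
#' Flips the time axis of each trial independently; channels, trials, sampling
#' rate and time axis metadata are preserved.  Applying it twice returns the
#' input bit-exactly.  Time-reversed data serve as surrogates for the
#' time-reversal causality test ([tr_ggc()]).
#'
#' @param X a [trials_array()].
#' @return a [trials_array()] with reversed time axis per trial.
#' @export
time_reverse <- function(X) {
  stopifnot(inherits(X, "trials_array"))
  n <- dim(X$data)[1]
  out <- X
  out$data <- X$data[n:1, , , drop = FALSE]
  out
}

#' Restrict a trials array to a time window
#'
#' @param X a [trials_array()] with a time axis.
#' @param from,to window bounds in the units of `X$times` (inclusive).
#' @return a [trials_array()] holding the samples inside the window.
#' @export
time_window <- function(X, from, to) {
  stopifnot(inherits(X, "trials_array"))
  if (is.null(X$times)) stop_trggc("'X' carries no time axis")
  keep <- which(X$times >= from & X$times <= to)
  if (length(keep) < 4) stop_trggc("time window contains too few samples")
  trials_array(X$data[keep, , , drop = FALSE], fs = X$fs,
               times = X$times[keep], time_unit = X$time_unit)
}
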