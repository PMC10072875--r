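#' Uniformly sampled continuous signal
#'
#' The basic container for a 1-D recording: ECoG, a photometry channel, a
#' membrane-voltage sweep, or a derived trace such as band power or dF/F.
#' Stored as a numeric vector with sampling rate, start time, channel label
#' and units carried as attributes.
#'
#' @param values Numeric vector of samples (volts for electrophysiology,
#'   arbitrary fluorescence units for photometry). Must be finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds relative to session start.
#' @param label Channel name.
#' @param units Unit string (e.g. "V", "mV", "a.u.").
#' @return An object of class `cont_signal`.
#' @examples
#' s <- cont_signal(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), fs = 1000)
#' signal_duration(s)
#' @export
cont_signal <- function(values, fs, t0 = 0, label = "signal", units = "a.u.") {
  values <- as.numeric(values)
  if (length(values) < 1) stop("signal must contain at least one sample")
  if (!all(is.finite(values))) stop("signal samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  fs <- as.numeric(fs)
  structure(values,
    fs = fs, t0 = as.numeric(t0), label = as.character(label),
    units = as.character(units), class = "cont_signal"
  )
}

#' @export
print.cont_signal <- function(x, ...) {
  cat(sprintf(
    "<cont_signal> %s: %d samples @ %g Hz (%.3f s), t0 = %g s, units = %s\n",
    attr(x, "label"), length(x), attr(x, "fs"),
    length(x) / attr(x, "fs"), attr(x, "t0"), attr(x, "units")
  ))
  invisible(x)
}

#' @rdname cont_signal
#' @param x A `cont_signal`.
#' @export
signal_fs <- function(x) attr(x, "fs")

#' @rdname cont_signal
#' @export
signal_t0 <- function(x) attr(x, "t0")

#' @rdname cont_signal
#' @export
signal_duration <- function(x) length(x) / attr(x, "fs")

#' Sample times of a continuous signal
#'
#' @param x A `cont_signal`.
#' @return Numeric vector of absolute times in seconds (0-based sample
#'   indexing: sample i sits at `t0 + (i - 1) / fs`).
#' @export
signal_times <- function(x) {
  attr(x, "t0") + (seq_along(x) - 1) / attr(x, "fs")
}

#' @export
as_tibble.cont_signal <- function(x, ...) {
  tibble::tibble(time_s = signal_times(x), value = as.numeric(x))
}

#' Extract a half-open time window [from, to) from a signal
#'
#' @param x A `cont_signal`.
#' @param from,to Window edges in seconds (absolute, same time base as `t0`).
#' @return Numeric vector of the samples whose times fall in `[from, to)`.
#' @export
signal_window <- function(x, from, to) {
  t <- signal_times(x)
  as.numeric(x)[t >= from & t < to]
}

#' Decimate a signal with an anti-alias filter
#'
#' Low-passes at 80% of the new Nyquist frequency (4th-order Butterworth,
#' zero-phase) and subsamples. Used to bring 30 kHz ECoG down to rates where
#' wavelet analysis below 100 Hz is tractable.
#'
#' @param x A `cont_signal`.
#' @param fs_out Target sampling rate; must divide `fs` evenly.
#' @return A `cont_signal` at `fs_out`.
#' @export
decimate_signal <- function(x, fs_out) {
  fs <- signal_fs(x)
  if (fs_out >= fs) return(x)
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-9) stop("fs_out must divide fs evenly")
  q <- round(q)
  bf <- signal::butter(4, 0.8 / q, type = "low")
  y <- signal::filtfilt(bf, as.numeric(x))
  cont_signal(y[seq(1, length(y), by = q)],
    fs = fs_out, t0 = signal_t0(x),
    label = attr(x, "label"), units = attr(x, "units")
  )
}

# internal: deterministic child seed derivation (counter-based, < 2^31)
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}
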