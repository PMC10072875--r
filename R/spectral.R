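#' Morlet continuous-wavelet spectrogram
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (center frequency `omega0`, default 6), evaluated on an arbitrary
#' frequency grid. Power is the squared modulus of the coefficients; the time
#' axis matches the input samples. Edge samples inside the cone of influence
#' at each frequency are retained but flagged in `coi_s`.
#'
#' @param x A [cont_signal].
#' @param freqs_hz Frequency grid (Hz), strictly increasing, all below
#'   Nyquist. Defaults to 48 log-spaced points over 1-100 Hz (clipped to
#'   Nyquist).
#' @param omega0 Morlet center frequency (non-dimensional), default 6.
#' @return An object of class `spectrogram`: list with `power`
#'   (freq x time matrix, >= 0), `freqs_hz`, `times_s`, `fs`, `coi_s`
#'   (e-folding cone-of-influence time per frequency) and `params`.
#' @examples
#' s <- cont_signal(sin(2 * pi * 10 * seq(0, 2, by = 1 / 250)), fs = 250)
#' sp <- morlet_cwt(s, freqs_hz = 2:40)
#' sp$freqs_hz[which.max(rowMeans(sp$power))]
#' @export
morlet_cwt <- function(x, freqs_hz = NULL, omega0 = 6) {
  fs <- signal_fs(x)
  if (is.null(freqs_hz)) {
    fmax <- min(100, fs / 2 * 0.95)
    freqs_hz <- exp(seq(log(1), log(fmax), length.out = 48))
  }
  if (any(diff(freqs_hz) <= 0)) stop("freqs_hz must be strictly increasing")
  if (max(freqs_hz) >= fs / 2) stop("frequencies at or above Nyquist (", fs / 2, " Hz)")
  n <- length(x)
  if (n < 3 * fs / min(freqs_hz)) {
    warning("signal shorter than 3 cycles of the lowest frequency; ",
            "low-frequency rows are COI-dominated")
  }
  dt <- 1 / fs
  m <- stats::nextn(n, 2)
  xf <- stats::fft(c(as.numeric(x), rep(0, m - n)))
  omega <- 2 * pi * (0:(m - 1)) / (m * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  # Fourier wavelength of the Morlet: lambda = 4*pi*s / (w0 + sqrt(2 + w0^2))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  power <- matrix(0, length(freqs_hz), n)
  for (i in seq_along(freqs_hz)) {
    s <- 1 / (freqs_hz[i] * fourier_factor)
    psi <- ifelse(omega > 0,
      pi^(-0.25) * exp(-(s * omega - omega0)^2 / 2), 0)
    norm <- sqrt(2 * pi * s / dt)
    w <- stats::fft(xf * norm * psi, inverse = TRUE) / m
    power[i, ] <- Mod(w[seq_len(n)])^2
  }
  structure(list(
    power = power, freqs_hz = freqs_hz, times_s = signal_times(x), fs = fs,
    coi_s = sqrt(2) / (freqs_hz * fourier_factor),
    params = list(omega0 = omega0)
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%.2f-%.2f Hz) x %d times (%.2f s)\n",
    length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
    length(x$times_s), diff(range(x$times_s))))
  invisible(x)
}

#' @export
as_tibble.spectrogram <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times_s, each = length(x$freqs_hz)),
    freq_hz = rep(x$freqs_hz, times = length(x$times_s)),
    power = as.numeric(x$power)
  )
}

#' Standard frequency bands
#'
#' The bands used throughout the analysis: the SWD fundamental
#' (modified theta, 7-10 Hz) and second-harmonic beta (10-20 Hz) pair, plus
#' the broader 4-8, 8-12, 12-30, 30-50 (low gamma) and 60-90 Hz (high gamma)
#' set used for cue-locked power.
#'
#' @return A tibble with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  tibble::tibble(
    name = c("theta", "beta", "b4_8", "b8_12", "b12_30", "b30_50", "b60_90"),
    lo_hz = c(7, 10, 4, 8, 12, 30, 60),
    hi_hz = c(10, 20, 8, 12, 30, 50, 90)
  )
}

#' Band power over time from a spectrogram
#'
#' Averages spectrogram rows whose frequency falls in `[lo_hz, hi_hz]` at each
#' time point. With `normalize = "peak_log10"` the spectrogram is first
#' divided by its single global maximum and log10-transformed (all values
#' <= 0, global max exactly 0), matching peak-normalized log power; a
#' per-frequency peak normalization is available via `per_freq = TRUE`.
#'
#' @param spec A `spectrogram`.
#' @param lo_hz,hi_hz Band edges (Hz), 0 < lo < hi.
#' @param normalize "none" or "peak_log10".
#' @param per_freq If `TRUE`, peak-normalize each frequency row separately
#'   instead of by the global maximum.
#' @return A [cont_signal] of band power on the spectrogram's time base.
#' @export
band_power <- function(spec, lo_hz, hi_hz, normalize = c("none", "peak_log10"),
                       per_freq = FALSE) {
  normalize <- match.arg(normalize)
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("band edges must satisfy 0 < lo < hi")
  rows <- which(spec$freqs_hz >= lo_hz & spec$freqs_hz <= hi_hz)
  if (length(rows) == 0) stop("no spectrogram frequencies inside [", lo_hz,
    ", ", hi_hz, "] Hz")
  p <- spec$power
  units <- "power"
  if (normalize == "peak_log10") {
    if (per_freq) {
      mx <- apply(p, 1, max)
      if (any(mx <= 0)) stop("cannot peak-normalize: a frequency row is all zero")
      p <- log10(sweep(p, 1, mx, "/"))
    } else {
      mx <- max(p)
      if (mx <= 0) stop("cannot peak-normalize an all-zero spectrogram")
      p <- log10(p / mx)
    }
    units <- "log10(norm power)"
  }
  bp <- colMeans(p[rows, , drop = FALSE])
  fs_spec <- 1 / stats::median(diff(spec$times_s))
  cont_signal(bp, fs = fs_spec, t0 = spec$times_s[1],
    label = sprintf("power %g-%g Hz", lo_hz, hi_hz), units = units)
}

#' Event-aligned power traces
#'
#' Cuts a band-power (or any continuous) trace into per-event segments over a
#' half-open window `[event - pre_s, event + post_s)`, with group means and
#' variances keyed by labels (e.g. cue length x accuracy). Events whose
#' window falls outside the recording are dropped with a warning, not an
#' error.
#'
#' @param power A [cont_signal].
#' @param events_s Event times (s), same time base as the signal.
#' @param pre_s,post_s Window extent before/after each event.
#' @param labels Optional data frame (one row per event) of grouping labels.
#' @return An object of class `aligned_power`: `traces` (event x time
#'   matrix), `time_s` (relative axis), `labels` (tibble, with `.kept` rows
#'   only), and `summary` — a tibble of per-group `mean` and `var` traces in
#'   long form.
#' @export
align_power <- function(power, events_s, pre_s = 1, post_s = 5, labels = NULL) {
  fs <- signal_fs(power)
  t0 <- signal_t0(power)
  n <- length(power)
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  centers <- round((events_s - t0) * fs) + 1
  keep <- centers - n_pre >= 1 & centers + n_post - 1 <= n
  if (!all(keep)) {
    warning(sum(!keep), " event(s) too near the recording edge; dropped")
  }
  if (!any(keep)) stop("no events with a complete window")
  centers <- centers[keep]
  traces <- t(vapply(centers, function(c0) {
    as.numeric(power)[(c0 - n_pre):(c0 + n_post - 1)]
  }, numeric(n_pre + n_post)))
  time_rel <- (seq_len(n_pre + n_post) - n_pre - 1) / fs
  if (is.null(labels)) labels <- tibble::tibble(group = rep("all", length(events_s)))
  labels <- tibble::as_tibble(labels)[keep, , drop = FALSE]
  grp <- interaction(labels, drop = TRUE)
  summ <- dplyr::bind_rows(lapply(levels(grp), function(g) {
    rows <- traces[grp == g, , drop = FALSE]
    tibble::tibble(
      group = g, time_s = time_rel,
      mean = colMeans(rows),
      var = if (nrow(rows) > 1) apply(rows, 2, stats::var) else rep(0, ncol(rows)),
      n = nrow(rows)
    )
  }))
  structure(list(traces = traces, time_s = time_rel, labels = labels,
                 summary = summ),
            class = "aligned_power")
}

#' Stimulus-train band-power response vs baseline
#'
#' For each optogenetic stimulus train, compares mean band power during the
#' train with the 0.5 s immediately preceding it.
#'
#' @param power A [cont_signal] of (typically peak-normalized log) band power.
#' @param train_onsets_s Train onset times (s).
#' @param train_len_s Train duration (s), shared by all trains.
#' @param baseline_s Baseline length before each onset (default 0.5 s).
#' @return A tibble with one row per train: `onset_s`, `baseline`, `stim`,
#'   `delta` (stim - baseline).
#' @export
stim_band_response <- function(power, train_onsets_s, train_len_s,
                               baseline_s = 0.5) {
  ord <- order(train_onsets_s)
  on <- train_onsets_s[ord]
  if (length(on) > 1 && any(diff(on) < train_len_s)) {
    stop("overlapping stimulus trains")
  }
  t_lo <- signal_t0(power)
  t_hi <- t_lo + signal_duration(power)
  if (any(on - baseline_s < t_lo) || any(on + train_len_s > t_hi)) {
    stop("stimulus train window outside the recording")
  }
  purrr::map_dfr(on, function(o) {
    tibble::tibble(
      onset_s = o,
      baseline = mean(signal_window(power, o - baseline_s, o)),
      stim = mean(signal_window(power, o, o + train_len_s))
    )
  }) |> dplyr::mutate(delta = .data$stim - .data$baseline)
}
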