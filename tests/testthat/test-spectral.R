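test_that("CWT localizes pure tones to the nearest grid frequency", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  freqs <- exp(seq(log(4), log(90), length.out = 40))
  for (f0 in c(10, 8, 40)) {
    x <- cont_signal(sin(2 * pi * f0 * t), fs = fs)
    # independent oracle: FFT peak
    expect_equal(fft_peak_hz(as.numeric(x), fs), f0, tolerance = 0.3 / f0)
    spec <- morlet_cwt(x, freqs_hz = freqs)
    got <- spec$freqs_hz[which.max(rowMeans(spec$power))]
    grid_nearest <- freqs[which.min(abs(freqs - f0))]
    expect_equal(got, grid_nearest)
  }
})

test_that("CWT of a zero signal is identically zero and Nyquist is enforced", {
  x <- cont_signal(rep(0, 500), fs = 100)
  spec <- suppressWarnings(morlet_cwt(x, freqs_hz = c(5, 10, 20)))
  expect_true(all(spec$power == 0))
  expect_equal(dim(spec$power), c(3, 500))
  expect_error(morlet_cwt(x, freqs_hz = c(10, 60)), "Nyquist")
})

test_that("two simultaneous tones yield two local maxima at their grid bins", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  x <- cont_signal(sin(2 * pi * 8 * t) + sin(2 * pi * 40 * t), fs = fs)
  freqs <- exp(seq(log(4), log(90), length.out = 48))
  spec <- morlet_cwt(x, freqs_hz = freqs)
  prof <- rowMeans(spec$power)
  is_peak <- which(diff(sign(diff(prof))) == -2) + 1
  peak_f <- spec$freqs_hz[is_peak]
  expect_true(any(abs(peak_f - 8) < diff(range(freqs[1:2])) + 8 * 0.06))
  expect_true(any(abs(peak_f - 40) < 40 * 0.06))
  expect_equal(length(peak_f), 2)
})

test_that("frequency recovery error is at most one grid step from 4-90 Hz", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  freqs <- exp(seq(log(4), log(90), length.out = 48))
  for (i in seq(1, 48, by = 6)) {
    f0 <- freqs[i]
    spec <- morlet_cwt(cont_signal(sin(2 * pi * f0 * t), fs = fs),
                       freqs_hz = freqs)
    got_idx <- which.max(rowMeans(spec$power))
    expect_lte(abs(got_idx - i), 1)
  }
})

test_that("time-averaged tone power is duration-invariant (Parseval-style)", {
  fs <- 200
  freqs <- exp(seq(log(4), log(50), length.out = 24))
  pw <- vapply(c(2, 4, 8), function(dur) {
    t <- seq(0, dur, by = 1 / fs)
    spec <- morlet_cwt(cont_signal(sin(2 * pi * 10 * t), fs = fs),
                       freqs_hz = freqs)
    # time-average outside the 0.5 s cone-of-influence margins
    core <- spec$times_s >= 0.5 & spec$times_s <= dur - 0.5
    mean(colSums(spec$power[, core]))
  }, numeric(1))
  expect_lt(max(abs(pw / pw[1] - 1)), 0.02)
})

test_that("band power separates in-band from out-of-band tones", {
  fs <- 250
  t <- seq(0, 5, by = 1 / fs)
  spec <- morlet_cwt(cont_signal(sin(2 * pi * 8 * t), fs = fs),
                     freqs_hz = exp(seq(log(4), log(90), length.out = 48)))
  inband <- mean(as.numeric(band_power(spec, 7, 10)))
  out <- mean(as.numeric(band_power(spec, 30, 50)))
  expect_gt(inband / out, 10)
  expect_error(band_power(spec, 91, 95), "inside")
  expect_error(band_power(spec, 10, 7), "lo < hi")
})

test_that("peak-normalized log10 spectrogram has global max exactly 0", {
  g <- gen_ecog(30, 500, swd_rate_per_min = 2, seed = 5)
  spec <- morlet_cwt(g$signal, freqs_hz = seq(4, 90, by = 2))
  full <- log10(spec$power / max(spec$power))
  expect_identical(max(full), 0)
  bp <- band_power(spec, 7, 10, normalize = "peak_log10")
  expect_lte(max(as.numeric(bp)), 0)
  # per-frequency variant normalizes every row to peak 0
  bpf <- band_power(spec, 4, 90, normalize = "peak_log10", per_freq = TRUE)
  expect_lte(max(as.numeric(bpf)), 0)
})

test_that("white-noise band power matches the flat-spectrum level", {
  withr::with_seed(8, x <- rnorm(20000))
  spec <- morlet_cwt(cont_signal(x, fs = 200),
                     freqs_hz = seq(10, 80, by = 2))
  prof <- rowMeans(spec$power)
  # flat spectrum: per-frequency mean power varies within sampling error
  expect_lt(stats::sd(prof) / mean(prof), 0.15)
})

test_that("align_power groups means and variances correctly", {
  x <- cont_signal(rep(2.5, 1000), fs = 100)
  al <- align_power(x, events_s = c(2, 4, 6), pre_s = 0.5, post_s = 0.5)
  expect_true(all(al$traces == 2.5))
  expect_true(all(al$summary$mean == 2.5))
  expect_true(all(al$summary$var == 0))
  # single trial: variance identically zero
  al1 <- align_power(x, events_s = 5, pre_s = 0.5, post_s = 0.5)
  expect_true(all(al1$summary$var == 0))
  # edge events dropped with a warning, not an error
  expect_warning(align_power(x, events_s = c(0.1, 5), pre_s = 0.5,
                             post_s = 0.5), "dropped")
})

test_that("a power step at the event lands at t=0 within one bin", {
  fs <- 100
  v <- c(rep(1, 500), rep(2, 500))
  al <- align_power(cont_signal(v, fs = fs), events_s = 5, pre_s = 1,
                    post_s = 1)
  m <- al$summary$mean[al$summary$time_s < -1 / fs]
  p <- al$summary$mean[al$summary$time_s >= 1 / fs]
  expect_true(all(m == 1))
  expect_true(all(p == 2))
})

test_that("stim_band_response pairs each train with its 0.5 s baseline", {
  fs <- 100
  n <- 200 * fs
  onsets <- seq(30, by = 30, length.out = 5)
  v <- rep(1, n)
  t <- (seq_len(n) - 1) / fs
  for (o in onsets) v[t >= o & t < o + 2] <- 3 # injected gamma-power step
  resp <- stim_band_response(cont_signal(v, fs = fs), onsets, train_len_s = 2)
  expect_equal(nrow(resp), 5)
  expect_true(all(resp$stim > resp$baseline))
  expect_equal(resp$delta, rep(2, 5))
  # no injected power: paired difference centered at zero
  flat <- stim_band_response(cont_signal(rep(1, n), fs = fs), onsets, 2)
  expect_true(all(flat$delta == 0))
  expect_error(stim_band_response(cont_signal(v, fs = fs), c(30, 31), 2),
               "overlapping")
})
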