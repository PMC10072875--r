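test_that("generators are pure functions of (params, seed)", {
  a <- gen_ecog(30, 500, 1, seed = 3)
  b <- gen_ecog(30, 500, 1, seed = 3)
  expect_identical(as.numeric(a$signal), as.numeric(b$signal))
  expect_identical(a$truth, b$truth)

  s1 <- gen_session(20, seed = 9)
  s2 <- gen_session(20, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  r1 <- gen_photometry(s1, seed = 4)
  r2 <- gen_photometry(s1, seed = 4)
  expect_identical(as.numeric(r1$sig470), as.numeric(r2$sig470))

  c1 <- gen_noisy_current(0.2, 2000, seed = 5)
  c2 <- gen_noisy_current(0.2, 2000, seed = 5)
  expect_identical(as.numeric(c1), as.numeric(c2))
})

test_that("ECoG at rate 0 has no events and no absence-band peak", {
  g <- gen_ecog(120, 500, swd_rate_per_min = 0, seed = 2)
  expect_equal(nrow(g$truth), 0)
  spec <- morlet_cwt(g$signal, freqs_hz = seq(2, 40, by = 1))
  prof <- rowMeans(spec$power)
  # 1/f background: no narrowband excess in 7-10 Hz over its neighborhood
  inband <- mean(prof[spec$freqs_hz >= 7 & spec$freqs_hz <= 10])
  nearby <- mean(prof[spec$freqs_hz >= 4 & spec$freqs_hz < 7])
  expect_lt(inband, 2 * nearby)
  expect_error(gen_ecog(60, 500, swd_rate_per_min = -1), "non-negative")
})

test_that("ECoG event count follows the Poisson law", {
  # 600 s at 0.5/min: lambda = 5; realized count within the Poisson 99% band
  counts <- vapply(1:5, function(s) {
    nrow(gen_ecog(600, 250, swd_rate_per_min = 0.5, seed = s)$truth)
  }, numeric(1))
  lims <- qpois(c(0.005, 0.995), lambda = 5)
  expect_true(all(counts >= lims[1] & counts <= lims[2]))
  # placement honors validity invariants
  g <- gen_ecog(600, 250, 0.5, seed = 1)
  expect_true(all(g$truth$end_s - g$truth$start_s >= 2))
  expect_true(all(g$truth$end_s - g$truth$start_s <= 30))
  expect_true(all(g$truth$f0_hz >= 7 & g$truth$f0_hz <= 10))
})

test_that("session generator honors degenerate psychometric parameters", {
  all_ok <- gen_session(30, psycho = list(p_correct = 1, p_omit = 0), seed = 1)
  expect_true(all(all_ok$outcome == "correct"))

  persev <- gen_session(30, psycho = list(p_persev = 1, p_omit = 0), seed = 2)
  expect_true(all(persev$chosen_port == persev$chosen_port[1]))

  expect_error(gen_session(10, psycho = list(p_correct = 1.2)), "outside")
})

test_that("session accuracy converges to p_correct (binomial oracle)", {
  hits <- 0; n_resp <- 0
  for (s in 1:10) {
    ses <- gen_session(100, psycho = list(p_correct = 0.5, p_omit = 0),
                       seed = s)
    hits <- hits + sum(ses$outcome == "correct")
    n_resp <- n_resp + nrow(ses)
  }
  ci <- qbinom(c(0.005, 0.995), n_resp, 0.5) / n_resp
  expect_gte(hits / n_resp, ci[1])
  expect_lte(hits / n_resp, ci[2])
})

test_that("session timestamps are structurally consistent incl. 30 s timeout", {
  s <- gen_session(50, psycho = list(p_correct = 0.5, p_omit = 0.1), seed = 7)
  expect_true(all(abs(s$cue_off_s - s$cue_on_s - s$cue_length_s) < 1e-9))
  resp <- !is.na(s$choice_time_s)
  expect_true(all(s$choice_time_s[resp] >= s$cue_on_s[resp]))
  # after an incorrect trial the next init comes >= 30 s after the choice
  inc <- which(s$outcome == "incorrect")
  inc <- inc[inc < nrow(s)]
  expect_true(all(s$init_time_s[inc + 1] - s$choice_time_s[inc] >= 30))
})

test_that("photometry generator produces the constructed dF/F peak exactly", {
  s <- make_session(rep("correct", 3), cue_len = 2)
  truth <- tibble::tibble(amp = 0.05, latency_s = 0.2, rise_tau_s = 0.15,
                          decay_tau_s = 0.6)
  rec <- gen_photometry(s, truth, motion_scale = 0, noise_sd = 0, seed = 1)
  dff <- compute_dff(rec$sig470)
  aligned <- segment_trials(dff, s)
  feats <- trial_features(aligned)
  expect_equal(feats$peak_raw, rep(0.05, 3), tolerance = 1e-6 / 0.05)
  # zero-amplitude transients leave dF/F flat
  rec0 <- gen_photometry(s, dplyr::mutate(truth, amp = 0),
                         motion_scale = 0, noise_sd = 0, seed = 1)
  expect_lt(max(abs(as.numeric(compute_dff(rec0$sig470)))), 1e-12)
  expect_error(gen_photometry(s, truth, noise_sd = -1), "non-negative")
})

test_that("laminar forward model is the exact inverse of the CSD", {
  lam <- gen_laminar(8, amplitude_per_intensity = c(2), n_trials = 1,
                     noise_sd = 0, seed = 1)
  map <- compute_csd(lam$sweeps[[1]], spacing_um = lam$spacing_um, fs = lam$fs)
  # extremum sits exactly at the injected sink channel
  ext <- arrayInd(which.min(map$values), dim(map$values))
  expect_equal(map$channels[ext[1]], 8)
  # injected profile recovered (up to the time-course scale) to machine
  # precision at the peak sample
  peak_col <- ext[2]
  scale <- map$values[ext[1], peak_col] / lam$truth$profile[8]
  expect_equal(map$values[, peak_col], lam$truth$profile[2:15] * scale,
               tolerance = 1e-10)
  expect_error(gen_laminar(1), "interior")
  expect_error(gen_laminar(16), "interior")
})

test_that("laminar amplitude scales monotonically with intensity", {
  lam <- gen_laminar(8, amplitude_per_intensity = 1:5, n_trials = 2,
                     noise_sd = 1e-4, seed = 3)
  curve <- amplitude_curve(lam, channels = 7:9, sign = "sink")
  expect_true(all(diff(abs(curve$amplitude)) > 0))
})

test_that("IPSP sweeps respect the release probability at the extremes", {
  all_ipsp <- gen_ipsp_sweeps(3, p_release = 1, ipsp_amp_mv = 1,
                              noise_sd_mv = 0, seed = 1)
  expect_equal(failure_rate(ipsp_failures(all_ipsp)), 0)
  none <- gen_ipsp_sweeps(3, p_release = 0, ipsp_amp_mv = 1,
                          noise_sd_mv = 0, seed = 1)
  expect_equal(failure_rate(ipsp_failures(none)), 100)
  # TTL geometry: 20 pulses at 40 Hz over 0.5 s
  expect_equal(length(all_ipsp[[1]]$light_ttl_times_s), 20)
  expect_equal(diff(all_ipsp[[1]]$light_ttl_times_s)[1], 1 / 40)
})

test_that("failure rate at p_release 0.5 follows the binomial law", {
  sw <- gen_ipsp_sweeps(50, p_release = 0.5, ipsp_amp_mv = 1,
                        noise_sd_mv = 0.02, seed = 11)
  est <- failure_rate(ipsp_failures(sw)) / 100
  n <- 50 * 20
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("noisy current matches its stated statistics and bandwidth", {
  cur <- gen_noisy_current(5, 5000, seed = 2)
  expect_equal(mean(as.numeric(cur)), 150, tolerance = 1 / 150)
  ac <- as.numeric(cur) - mean(as.numeric(cur))
  sp <- Mod(stats::fft(ac))^2
  f <- (seq_along(sp) - 1) * 5000 / length(sp)
  half <- f <= 2500
  high <- sum(sp[half & f > 150])
  expect_lt(high / sum(sp[half]), 0.01)
  expect_error(gen_noisy_current(1, 500), "1 kHz")
})

test_that("LIF spike sweeps: no inhibition leaves counts equal in expectation", {
  cur <- gen_noisy_current(0.5, 10000, seed = 3)
  sw <- gen_spike_sweeps(cur, inhibition_fraction = 0, n_trials = 6, seed = 4)
  cond <- vapply(sw, function(x) x$condition, character(1))
  cnt <- vapply(sw, function(x) length(x$spike_times_s), numeric(1))
  m0 <- mean(cnt[cond == "no_light"]); m1 <- mean(cnt[cond == "continuous_light"])
  expect_lt(abs(m0 - m1), 3 * sd(cnt) / sqrt(6) + 1)
  # subthreshold DC alone evokes nothing
  dc <- cont_signal(rep(30, 5000), fs = 10000, units = "pA")
  quiet <- gen_spike_sweeps(dc, 0, n_trials = 1,
                            lif_params = list(trial_noise_pa = 0), seed = 1)
  expect_equal(length(quiet[[1]]$spike_times_s), 0)
})

test_that("LIF inhibition calibration hits the requested reduction", {
  cur <- gen_noisy_current(0.5, 10000, seed = 5)
  sw <- gen_spike_sweeps(cur, inhibition_fraction = 0.5, n_trials = 12,
                         seed = 6)
  cond <- vapply(sw, function(x) x$condition, character(1))
  cnt <- vapply(sw, function(x) length(x$spike_times_s), numeric(1))
  red <- spike_reduction(cnt[cond == "no_light"],
                         cnt[cond == "continuous_light"])
  expect_gt(red, 35)
  expect_lt(red, 65)
})
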