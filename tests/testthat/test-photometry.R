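test_that("deinterleave splits alternating samples and is invertible", {
  a <- c(1, 10, 2, 20, 3, 30, 4, 40)
  raw <- cont_signal(a, fs = 40)
  rec <- deinterleave(raw, phase = 0)
  expect_equal(as.numeric(rec$sig470), c(1, 2, 3, 4))
  expect_equal(as.numeric(rec$ref405), c(10, 20, 30, 40))
  expect_equal(signal_fs(rec$sig470), 20)
  # true acquisition times: channels offset by one raw sample
  expect_equal(signal_t0(rec$ref405) - signal_t0(rec$sig470), 1 / 40)
  # phase swap exchanges channel assignment
  rec1 <- deinterleave(raw, phase = 1)
  expect_equal(as.numeric(rec1$ref405), c(1, 2, 3, 4))
  expect_equal(as.numeric(rec1$sig470), c(10, 20, 30, 40))
  # re-interleaving reproduces the input
  merged <- as.numeric(rbind(as.numeric(rec$sig470), as.numeric(rec$ref405)))
  expect_identical(merged, a)
  # odd length: last sample dropped with warning
  expect_warning(deinterleave(cont_signal(1:7, fs = 40)), "odd")
})

test_that("motion correction recovers exact regression coefficients", {
  withr::with_seed(1, ref <- rnorm(200, mean = 5))
  sig <- 2 * ref + 3
  out <- motion_correct(cont_signal(sig, fs = 20), cont_signal(ref, fs = 20))
  fit <- attr(out, "fit")
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 3, tolerance = 1e-10)
  # perfectly explained: residual trace is the restored constant mean
  expect_equal(as.numeric(out), rep(mean(sig), 200), tolerance = 1e-10)
  expect_error(motion_correct(cont_signal(sig, fs = 20),
                              cont_signal(rep(1, 200), fs = 20)), "variance")
})

test_that("uncorrelated reference leaves the signal nearly untouched", {
  withr::with_seed(2, {
    sig <- 1 + 0.05 * sin(seq(0, 20, length.out = 1000))
    ref <- rnorm(1000)
  })
  out <- motion_correct(cont_signal(sig, fs = 20), cont_signal(ref, fs = 20))
  expect_lt(abs(attr(out, "fit")$a), 0.01)
  expect_gt(stats::cor(as.numeric(out), sig), 0.99)
})

test_that("shared motion artifact is removed by the isosbestic regression", {
  s <- make_session(rep("correct", 5), cue_len = 2)
  truth <- tibble::tibble(amp = 0.06, latency_s = 0.2, rise_tau_s = 0.15,
                          decay_tau_s = 0.6)
  rec <- gen_photometry(s, truth, motion_scale = 2, noise_sd = 0, seed = 9)
  clean <- gen_photometry(s, truth, motion_scale = 0, noise_sd = 1e-9, seed = 9)
  out <- motion_correct(rec$sig470, rec$ref405)
  expect_gt(stats::cor(as.numeric(out), as.numeric(clean$sig470)), 0.99)
})

test_that("dF/F identities: constant, exact algebraic form, gain invariance", {
  expect_true(all(as.numeric(compute_dff(cont_signal(rep(3, 50), fs = 20))) == 0))
  # trace = m*(1 + x) with median(x) = 0 gives dff = x exactly
  x <- c(-0.2, -0.1, 0, 0.1, 0.3)
  tr <- cont_signal(7 * (1 + x), fs = 5)
  expect_equal(as.numeric(compute_dff(tr)), x, tolerance = 1e-12)
  # multiplicative gain drops out
  expect_equal(as.numeric(compute_dff(cont_signal(2 * as.numeric(tr), fs = 5))),
               as.numeric(compute_dff(tr)), tolerance = 1e-12)
  expect_error(compute_dff(cont_signal(c(-3, -2, -1), fs = 5)), "median")
})

test_that("segment_trials aligns, labels and drops edge trials", {
  s <- make_session(c("correct", "incorrect", "correct", "omission",
                      "correct", "incorrect", "correct", "correct",
                      "incorrect", "correct"), cue_len = 2)
  rec <- gen_photometry(s, motion_scale = 0, noise_sd = 1e-4, seed = 2)
  dff <- compute_dff(rec$sig470)
  al <- segment_trials(dff, s)
  expect_equal(nrow(al$traces), 10)
  expect_equal(al$labels$outcome, s$outcome)
  expect_equal(table(al$labels$outcome), table(s$outcome))
  expect_error(segment_trials(dff, s[0, ]), "empty")
  # constant dff: every row constant
  flat <- cont_signal(rep(1, 20 * 600), fs = 20)
  al2 <- segment_trials(compute_dff(flat), s)
  expect_true(all(al2$traces == 0))
})

test_that("outcome-dependent transients separate the group means", {
  s <- make_session(rep(c("correct", "incorrect"), 10), cue_len = 2)
  truth <- tibble::tibble(
    amp = ifelse(s$outcome == "correct", 0.08, 0.01),
    latency_s = 0.2, rise_tau_s = 0.15, decay_tau_s = 0.6)
  rec <- gen_photometry(s, truth, motion_scale = 0.5, noise_sd = 0.003,
                        seed = 3)
  feats <- process_photometry(rec, s)$features
  m <- tapply(feats$cue_mean, feats$outcome, mean)
  expect_gt(m[["correct"]], m[["incorrect"]])
})

test_that("trial features reproduce constructed values", {
  # hand-built aligned object: flat baseline, boxcar of 0.05 over the cue
  fs <- 20
  time_s <- seq(-1, 5 - 1 / fs, by = 1 / fs)
  v <- ifelse(time_s >= 0 & time_s < 2, 0.05, 0)
  aligned <- structure(list(
    traces = rbind(v, v), time_s = time_s,
    labels = tibble::tibble(index = 0:1, cue_length_s = 2,
                            outcome = c("correct", "incorrect")),
    fs = fs, baseline_window = c(-1, 0)
  ), class = "trial_aligned")
  f <- trial_features(aligned)
  expect_equal(f$baseline_mean, c(0, 0))
  expect_equal(f$cue_mean, c(0.05, 0.05))
  expect_equal(f$peak_amplitude, c(0.05, 0.05))
  expect_equal(ncol(dplyr::select(f, dplyr::starts_with("f_"))), 22)
  # flat trace: baseline equals cue mean, zero peak
  flat <- aligned
  flat$traces <- matrix(0.2, 2, length(time_s))
  f0 <- trial_features(flat)
  expect_equal(f0$baseline_mean, f0$cue_mean)
  expect_equal(f0$peak_amplitude, c(0, 0))
})

test_that("time-to-peak lands on the injected transient peak", {
  s <- make_session(rep("correct", 4), cue_len = 5)
  # kernel peaks where d/dt[(1-e^(-t/r))e^(-t/d)] = 0: t* = r*log(1+d/r)
  truth <- tibble::tibble(amp = 0.1, latency_s = 0.3, rise_tau_s = 0.15,
                          decay_tau_s = 0.6)
  t_star <- 0.3 + 0.15 * log(1 + 0.6 / 0.15)
  rec <- gen_photometry(s, truth, motion_scale = 0, noise_sd = 0, seed = 1)
  # motion-free, noise-free: dF/F computed directly (degenerate reference)
  feats <- trial_features(segment_trials(compute_dff(rec$sig470), s))
  expect_equal(mean(feats$time_to_peak_s), t_star, tolerance = 0.1 / t_star)
})

test_that("peak amplitude recovery is accurate at adequate SNR", {
  s <- make_session(rep("correct", 20), cue_len = 2)
  truth <- tibble::tibble(amp = 0.05, latency_s = 0.2, rise_tau_s = 0.15,
                          decay_tau_s = 0.6)
  rec <- gen_photometry(s, truth, motion_scale = 1, noise_sd = 0.005, seed = 8)
  feats <- process_photometry(rec, s)$features
  expect_lt(abs(mean(feats$peak_smoothed) - 0.05) / 0.05, 0.1)
})
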