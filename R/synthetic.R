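#' Synthetic ECoG with embedded spike-and-wave discharges
#'
#' Generates a 1/f-shaped Gaussian background band-limited to 0.1-100 Hz and
#' superimposes harmonic-rich spike-and-wave discharge (SWD) events: a
#' fundamental sine in the absence band (7-10 Hz), a half-weight second
#' harmonic, and a sharp "spike" component (rectified, exponentiated
#' sinusoid), all amplitude-windowed with 0.2 s cosine ramps. Event onsets
#' follow a Poisson process at `swd_rate_per_min`; durations and fundamentals
#' are drawn uniformly from the supplied ranges. Event RMS is `amp_rel` times
#' the background RMS (default 5).
#'
#' Generators are pure functions of their parameters and `seed`: the same call
#' returns bit-identical output.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 200).
#' @param swd_rate_per_min Expected SWD rate per minute (>= 0).
#' @param swd_params List: `amp_rel` (event RMS / background RMS),
#'   `dur_range_s` (length-2, within \[2, 30\] for rule-conforming events),
#'   `f0_range_hz` (within \[7, 10\] for rule-conforming events).
#' @param seed Integer RNG seed.
#' @return A list with `signal` (a [cont_signal], volts) and `truth`, a tibble
#'   of ground-truth events (`start_s`, `end_s`, `f0_hz`, `amp_rel`).
#' @examples
#' g <- gen_ecog(60, 500, swd_rate_per_min = 1, seed = 7)
#' nrow(g$truth)
#' @export
gen_ecog <- function(duration_s, fs = 1000, swd_rate_per_min = 0.3,
                     swd_params = list(), seed = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs < 200) stop("fs must be at least 200 Hz")
  if (swd_rate_per_min < 0) stop("swd_rate_per_min must be non-negative")
  p <- utils::modifyList(list(
    amp_rel = 5, dur_range_s = c(3, 12), f0_range_hz = c(7, 10)
  ), swd_params)
  withr::with_seed(seed, {
    n <- round(duration_s * fs)
    bg <- one_over_f_noise(n, fs, f_lo = 0.1, f_hi = 100)
    bg <- bg / stats::sd(bg) * 1e-4 # ~100 uV background RMS
    rms <- stats::sd(bg)
    n_ev <- stats::rpois(1, swd_rate_per_min * duration_s / 60)
    events <- list()
    x <- bg
    if (n_ev > 0) {
      taken <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(n_ev)) {
        dur <- stats::runif(1, p$dur_range_s[1], p$dur_range_s[2])
        if (dur + 1 >= duration_s) next
        # rejection-place to keep events separated by >= 2 s
        ok <- FALSE
        for (try in 1:50) {
          st <- stats::runif(1, 0.5, max(duration_s - dur - 0.5, 0.6))
          if (st + dur + 0.5 > duration_s) next
          ok <- nrow(taken) == 0 ||
            all(st > taken[, 2] + 2 | st + dur < taken[, 1] - 2)
          if (ok) break
        }
        if (!ok) next
        taken <- rbind(taken, c(st, st + dur))
        f0 <- stats::runif(1, p$f0_range_hz[1], p$f0_range_hz[2])
        idx <- which(signal_grid(n, fs) >= st & signal_grid(n, fs) < st + dur)
        tt <- (idx - 1) / fs - st
        wave <- swd_waveform(tt, f0)
        wave <- wave * cosine_ramp(length(idx), round(0.2 * fs))
        wave <- wave / stats::sd(wave) * p$amp_rel * rms
        x[idx] <- x[idx] + wave
        events[[length(events) + 1]] <- tibble::tibble(
          start_s = st, end_s = st + dur, f0_hz = f0, amp_rel = p$amp_rel
        )
      }
    }
    truth <- if (length(events)) dplyr::arrange(dplyr::bind_rows(events), .data$start_s)
      else tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          f0_hz = numeric(0), amp_rel = numeric(0))
    list(
      signal = cont_signal(x, fs = fs, label = "ecog", units = "V"),
      truth = truth
    )
  })
}

signal_grid <- function(n, fs) (seq_len(n) - 1) / fs

# fundamental + half-weight 2nd harmonic + sharp rectified spike component
swd_waveform <- function(t, f0) {
  sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
    0.8 * pmax(sin(2 * pi * f0 * t + pi / 3), 0)^6
}

cosine_ramp <- function(n, n_ramp) {
  w <- rep(1, n)
  m <- min(n_ramp, floor(n / 2))
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
    w[seq_len(m)] <- ramp
    w[n - m + seq_len(m)] <- rev(ramp)
  }
  w
}

# band-limited 1/f noise via frequency-domain synthesis
one_over_f_noise <- function(n, fs, f_lo = 0.1, f_hi = 100) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(f), 0)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = rep(0, n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Synthetic operant attention-task session
#'
#' Draws a trial sequence for the attentional engagement task (AET; cue length
#' varied pseudorandomly) or the variable-delay task (VDST; fixed cue after a
#' variable delay). Cue lengths and the correct side are assigned
#' pseudorandomly with near-equal counts; outcomes are drawn from the supplied
#' psychometric parameters; timestamps follow the trial structure, including
#' the 30 s timeout after incorrect choices.
#'
#' @param n_trials Number of trials (<= 100).
#' @param task "AET" or "VDST".
#' @param cue_lengths Cue lengths (s) to interleave (AET) or the single fixed
#'   cue length (VDST).
#' @param psycho List of psychometric parameters: `p_correct` and `p_omit`
#'   (each either a single probability or a named map cue length -> prob),
#'   `rt_meanlog`, `rt_sdlog`, `rt_incorrect_shift` (log-normal reaction-time
#'   parameters; incorrect trials draw with `rt_meanlog + rt_incorrect_shift`),
#'   `p_persev` (probability of repeating the previous port choice), and for
#'   VDST `delays_s`.
#' @param seed Integer RNG seed.
#' @return A [session_table].
#' @export
gen_session <- function(n_trials = 60, task = "AET", cue_lengths = c(5, 2, 0.5),
                        psycho = list(), seed = 1) {
  if (n_trials > 100) stop("sessions cap at 100 trials")
  cue_lengths <- as.numeric(unlist(cue_lengths))
  if (length(cue_lengths) == 0) stop("cue_lengths must be non-empty")
  p <- utils::modifyList(list(
    p_correct = 0.8, p_omit = 0.05, rt_meanlog = log(0.7), rt_sdlog = 0.4,
    rt_incorrect_shift = 0.35, p_persev = 0, delays_s = c(3, 4, 5)
  ), psycho)
  lookup <- function(map, cue) {
    if (length(map) == 1 && is.null(names(map))) return(as.numeric(map))
    v <- map[[as.character(cue)]]
    if (is.null(v)) stop("no psychometric value for cue length ", cue)
    as.numeric(v)
  }
  for (cl in cue_lengths) {
    for (nm in c("p_correct", "p_omit")) {
      v <- lookup(p[[nm]], cl)
      if (v < 0 || v > 1) stop(nm, " outside [0, 1]")
    }
  }
  if (p$p_persev < 0 || p$p_persev > 1) stop("p_persev outside [0, 1]")
  withr::with_seed(seed, {
    # near-equal counts: block-shuffled assignment
    cues <- rep(cue_lengths, length.out = n_trials)[sample.int(n_trials)]
    sides <- rep(c("L", "R"), length.out = n_trials)[sample.int(n_trials)]
    delays <- if (task == "VDST") {
      p$delays_s[sample.int(length(p$delays_s), n_trials, replace = TRUE)]
    } else rep(0, n_trials)
    rows <- vector("list", n_trials)
    t_now <- 5
    prev_choice <- NULL
    for (i in seq_len(n_trials)) {
      cue <- cues[i]
      init <- t_now
      cue_on <- init + delays[i]
      cue_off <- cue_on + cue
      omit <- stats::runif(1) < lookup(p$p_omit, cue)
      if (omit) {
        chosen <- NA_character_
        outcome <- "omission"
        choice <- NA_real_
        t_end <- cue_off + 5 # omission declared 5 s after cue termination
      } else {
        persev <- !is.null(prev_choice) && stats::runif(1) < p$p_persev
        if (persev) {
          chosen <- prev_choice
          correct <- chosen == sides[i]
        } else {
          correct <- stats::runif(1) < lookup(p$p_correct, cue)
          chosen <- if (correct) sides[i] else setdiff(c("L", "R"), sides[i])
        }
        outcome <- if (chosen == sides[i]) "correct" else "incorrect"
        shift <- if (outcome == "incorrect") p$rt_incorrect_shift else 0
        rt <- min(stats::rlnorm(1, p$rt_meanlog + shift, p$rt_sdlog), 4.9)
        choice <- cue_off + rt
        t_end <- choice + if (outcome == "incorrect") 30 else 2
        prev_choice <- chosen
      }
      rows[[i]] <- tibble::tibble(
        index = i - 1L, task = task, cue_length_s = cue, delay_s = delays[i],
        correct_port = sides[i], chosen_port = chosen,
        init_time_s = init, cue_on_s = cue_on, cue_off_s = cue_off,
        choice_time_s = choice, outcome = outcome
      )
      t_now <- t_end + stats::runif(1, 2, 5) # inter-trial interval
    }
    trials <- dplyr::bind_rows(rows)
    session_table(trials, session_duration_s = max(t_now, 60))
  })
}

#' Synthetic dual-wavelength fiber-photometry recording
#'
#' Emulates interleaved 470 nm (calcium-dependent) and 405 nm (isosbestic)
#' acquisition at 20 Hz per channel. The 470 channel carries GCaMP-like
#' cue-locked transients (difference-of-exponentials kernel) whose per-trial
#' amplitudes come from `truth`; both channels share a slow motion artifact
#' with per-channel scale, so the artifact is recoverable by least squares
#' from the isosbestic channel.
#'
#' @param session A [session_table] giving trial times.
#' @param truth A tibble with one row per trial: `amp` (dF/F units, >= 0),
#'   `latency_s`, `rise_tau_s`, `decay_tau_s` (> 0). Recycled if single-row.
#' @param motion_scale Scale of the shared motion artifact added to the 470
#'   channel (the 405 channel receives `0.8 * motion_scale`); 0 disables.
#' @param noise_sd Per-channel white-noise SD in raw fluorescence units
#'   relative to a baseline of 1.
#' @param fs Per-channel sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @return A list of class `photometry_recording`: `sig470`, `ref405`
#'   ([cont_signal]s), `trial_ttl_times_s`, and the `truth` used.
#' @export
gen_photometry <- function(session, truth = NULL, motion_scale = 0.5,
                           noise_sd = 0.005, fs = 20, seed = 1) {
  if (nrow(session) == 0) stop("session has no trials")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(truth)) {
    truth <- tibble::tibble(amp = 0.05, latency_s = 0.2,
                            rise_tau_s = 0.15, decay_tau_s = 0.6)
  }
  if (nrow(truth) == 1) truth <- truth[rep(1, nrow(session)), ]
  if (nrow(truth) != nrow(session)) stop("truth must have 1 or n_trials rows")
  if (any(truth$amp < 0)) stop("transient amplitudes must be >= 0")
  if (any(truth$rise_tau_s <= 0) || any(truth$decay_tau_s <= 0)) {
    stop("transient taus must be positive")
  }
  withr::with_seed(seed, {
    dur <- session_duration(session)
    n <- ceiling(dur * fs)
    t <- signal_grid(n, fs)
    transients <- rep(0, n)
    for (i in seq_len(nrow(session))) {
      on <- session$cue_on_s[i] + truth$latency_s[i]
      rel <- t - on
      sel <- rel >= 0
      if (!any(sel)) next
      kern <- (1 - exp(-rel[sel] / truth$rise_tau_s[i])) *
        exp(-rel[sel] / truth$decay_tau_s[i])
      kern <- kern / max(kern)
      transients[sel] <- transients[sel] + truth$amp[i] * kern
    }
    motion <- if (motion_scale > 0) {
      m <- stats::rnorm(n)
      bf <- signal::butter(2, min(0.5 / (fs / 2), 0.99), type = "low")
      m <- signal::filtfilt(bf, m)
      motion_scale * 0.02 * m / max(stats::sd(m), .Machine$double.eps)
    } else rep(0, n)
    b470 <- 1.0
    b405 <- 0.7
    sig470 <- b470 * (1 + transients) + motion + stats::rnorm(n, 0, noise_sd)
    ref405 <- b405 + 0.8 * motion + stats::rnorm(n, 0, noise_sd)
    structure(list(
      sig470 = cont_signal(sig470, fs = fs, label = "470nm", units = "a.u."),
      ref405 = cont_signal(ref405, fs = fs, label = "405nm", units = "a.u."),
      trial_ttl_times_s = session$init_time_s,
      truth = truth
    ), class = "photometry_recording")
  })
}

#' Synthetic laminar LFP sweeps with known sink/source geometry
#'
#' Builds 16-channel local-field-potential sweeps by placing a target
#' current-source-density (CSD) profile — a sink at `sink_channel` flanked by
#' balancing sources — and integrating it twice across depth (double
#' cumulative summation, plus free linear terms), so that the second-spatial-
#' derivative CSD recovers the injected pattern exactly at zero noise. The
#' time course is an alpha-function response at `latency_s` after stimulus
#' onset, scaled per stimulation intensity.
#'
#' @param sink_channel Interior channel index (2..15, 1-based) for the sink.
#' @param amplitude_per_intensity Numeric vector of response amplitudes
#'   (V/mm^2 at the sink peak), one per stimulation intensity; intensities are
#'   100..500 uA in 100 uA steps recycled to this length.
#' @param n_trials Sweeps per intensity.
#' @param latency_s Response peak latency after stimulus onset.
#' @param noise_sd Additive LFP noise SD (V).
#' @param fs Sampling rate (Hz).
#' @param seed Integer RNG seed.
#' @return A list of class `laminar_sweep_set`: `sweeps` (list of 16 x time
#'   matrices, volts), `stim_intensity_uA` per sweep, `fs`, `spacing_um`,
#'   `stim_onset_s`, and `truth` (the injected per-channel CSD profile and
#'   per-intensity amplitudes).
#' @export
gen_laminar <- function(sink_channel = 8, amplitude_per_intensity = 1:5,
                        n_trials = 10, latency_s = 0.006, noise_sd = 0,
                        fs = 25000, seed = 1) {
  if (sink_channel < 2 || sink_channel > 15) {
    stop("sink must sit on an interior channel (2..15): CSD is undefined on edges")
  }
  n_ch <- 16
  h_mm <- 0.1 # 100 um spacing
  withr::with_seed(seed, {
    dur <- 0.06
    n <- round(dur * fs)
    t <- signal_grid(n, fs)
    stim_onset <- 0.01
    rel <- t - stim_onset - latency_s + 0.003
    alpha <- ifelse(rel > 0, (rel / 0.003) * exp(1 - rel / 0.003), 0)
    # unit CSD depth profile: sink -1 flanked by +0.5 sources (balanced)
    prof <- rep(0, n_ch)
    prof[sink_channel] <- -1
    prof[sink_channel - 1] <- prof[sink_channel - 1] + 0.5
    prof[sink_channel + 1] <- prof[sink_channel + 1] + 0.5
    intensities <- rep(seq(100, 500, by = 100), length.out =
                         length(amplitude_per_intensity))
    sweeps <- list()
    sweep_int <- numeric(0)
    for (j in seq_along(amplitude_per_intensity)) {
      csd_jt <- outer(prof * amplitude_per_intensity[j], alpha) # ch x time, V/mm^2
      # integrate twice over depth: V[i+1] - 2V[i] + V[i-1] = w[i+1],
      # w[k] = -h^2 * csd[k-1]; w[1] = w[2] = 0 fixes the free linear terms
      w <- rbind(0, 0, csd_jt[2:(n_ch - 1), , drop = FALSE] * (-h_mm^2))
      v <- apply(apply(w, 2, cumsum), 2, cumsum)
      for (k in seq_len(n_trials)) {
        sweeps[[length(sweeps) + 1]] <-
          v + matrix(stats::rnorm(n_ch * n, 0, noise_sd), n_ch, n)
        sweep_int <- c(sweep_int, intensities[j])
      }
    }
    structure(list(
      sweeps = sweeps, stim_intensity_uA = sweep_int, fs = fs,
      spacing_um = 100, stim_onset_s = stim_onset,
      truth = list(profile = prof, amplitudes = amplitude_per_intensity,
                   intensities = intensities, latency_s = latency_s)
    ), class = "laminar_sweep_set")
  })
}

#' Synthetic 40 Hz IPSP-train sweeps with a release probability
#'
#' Each sweep delivers 20 TTL pulses at 40 Hz over 0.5 s. Each pulse
#' independently evokes (with probability `p_release`) a hyperpolarizing
#' exponential IPSP of amplitude `ipsp_amp_mv`, else nothing, on a -70 mV
#' baseline with additive Gaussian noise.
#'
#' @param n_trials Number of sweeps (>= 1).
#' @param p_release Per-pulse release probability in \[0, 1\].
#' @param ipsp_amp_mv IPSP amplitude (mV, magnitude of the hyperpolarization).
#' @param tau_s IPSP decay time constant.
#' @param noise_sd_mv Additive membrane noise SD.
#' @param fs Sampling rate (Hz).
#' @param seed Integer RNG seed.
#' @return A list of `intracellular_sweep` objects, each with `vm`
#'   ([cont_signal], mV), `light_ttl_times_s` (20 pulse times), `condition`
#'   = "train_40hz", and `released` (logical ground truth per pulse).
#' @export
gen_ipsp_sweeps <- function(n_trials = 5, p_release = 0.8, ipsp_amp_mv = 1,
                            tau_s = 0.008, noise_sd_mv = 0.05, fs = 10000,
                            seed = 1) {
  if (p_release < 0 || p_release > 1) stop("p_release must be in [0, 1]")
  if (n_trials < 1) stop("n_trials must be >= 1")
  withr::with_seed(seed, {
    dur <- 1
    n <- round(dur * fs)
    t <- signal_grid(n, fs)
    ttl <- 0.25 + (0:19) / 40
    lapply(seq_len(n_trials), function(k) {
      vm <- rep(-70, n) + stats::rnorm(n, 0, noise_sd_mv)
      released <- stats::runif(20) < p_release
      for (j in which(released)) {
        rel <- t - ttl[j]
        sel <- rel >= 0 & rel < 0.1
        rise <- 1 - exp(-rel[sel] / 0.0015)
        vm[sel] <- vm[sel] - ipsp_amp_mv * rise * exp(-rel[sel] / tau_s) /
          max(rise * exp(-rel[sel] / tau_s))
      }
      structure(list(
        vm = cont_signal(vm, fs = fs, label = "Vm", units = "mV"),
        stim_current = NULL, light_ttl_times_s = ttl,
        condition = "train_40hz", released = released
      ), class = "intracellular_sweep")
    })
  })
}

#' Noisy current-injection waveform
#'
#' The naturalistic stimulus used to evoke variable but repeatable spiking:
#' 150 pA DC plus white Gaussian noise convolved with a 3 ms alpha kernel and
#' low-pass filtered at 100 Hz, with the fluctuating component rescaled to a
#' 10 pA standard deviation.
#'
#' @param duration_s Waveform length (s).
#' @param fs Sampling rate (Hz, >= 1000).
#' @param seed Integer RNG seed.
#' @return A [cont_signal] in pA.
#' @export
gen_noisy_current <- function(duration_s = 0.5, fs = 10000, seed = 1) {
  if (fs < 1000) stop("fs must be at least 1 kHz")
  withr::with_seed(seed, {
    n <- round(duration_s * fs)
    w <- stats::rnorm(n)
    tau <- 0.003
    tk <- seq(0, 6 * tau, by = 1 / fs)
    kern <- (tk / tau) * exp(1 - tk / tau)
    ac <- stats::filter(c(w, rep(0, length(kern))), kern, sides = 1)
    ac <- as.numeric(ac)[seq_len(n)]
    ac[is.na(ac)] <- 0
    bf <- signal::butter(4, 100 / (fs / 2), type = "low")
    ac <- signal::filtfilt(bf, ac)
    ac <- ac / stats::sd(ac) * 10
    cont_signal(150 + ac, fs = fs, label = "Istim", units = "pA")
  })
}

#' Spiking sweeps from a leaky integrate-and-fire membrane
#'
#' Drives a leaky integrate-and-fire (LIF) neuron with a current waveform and
#' returns paired no-light / light sweeps. In light sweeps an added
#' hyperpolarizing conductance suppresses spiking; its strength is calibrated
#' internally (deterministic bisection on mean spike count over calibration
#' sweeps) so the expected spike-count reduction equals `inhibition_fraction`.
#'
#' LIF parameters: tau_m 20 ms, R 200 MOhm, V_rest -70 mV, threshold -50 mV,
#' reset -60 mV, refractory 2 ms — chosen to yield roughly 10-30 spikes per
#' 0.5 s under the standard noisy 150 pA injection.
#'
#' @param current A [cont_signal] in pA (see [gen_noisy_current()]); per-sweep
#'   frozen noise is added on top so trials vary.
#' @param inhibition_fraction Target fractional reduction of expected spike
#'   count in light sweeps, in \[0, 1\].
#' @param n_trials Sweeps per condition.
#' @param lif_params Optional overrides of the LIF parameters (named list).
#' @param seed Integer RNG seed.
#' @return A list of `intracellular_sweep` objects, conditions `no_light` and
#'   `continuous_light`, each with `vm` and `spike_times_s` ground truth.
#' @export
gen_spike_sweeps <- function(current, inhibition_fraction = 0.5, n_trials = 5,
                             lif_params = list(), seed = 1) {
  if (inhibition_fraction < 0 || inhibition_fraction > 1) {
    stop("inhibition_fraction must be in [0, 1]")
  }
  p <- utils::modifyList(list(
    tau_m = 0.02, R_mohm = 200, v_rest = -70, v_thresh = -50,
    v_reset = -60, refrac_s = 0.002, trial_noise_pa = 15
  ), lif_params)
  fs <- signal_fs(current)
  base_i <- as.numeric(current)
  run_lif <- function(i_pa, extra_hyper_pa) {
    dt <- 1 / fs
    v <- p$v_rest
    n <- length(i_pa)
    vm <- numeric(n)
    spikes <- numeric(0)
    refrac_until <- -1
    for (k in seq_len(n)) {
      tk <- (k - 1) * dt
      if (tk < refrac_until) {
        v <- p$v_reset
      } else {
        # R in MOhm * I in pA -> uV; scale to mV
        drive <- p$R_mohm * (i_pa[k] - extra_hyper_pa) * 1e-3
        v <- v + dt / p$tau_m * (p$v_rest - v + drive)
        if (v >= p$v_thresh) {
          spikes <- c(spikes, tk)
          vm[k] <- 20 # spike peak marker
          v <- p$v_reset
          refrac_until <- tk + p$refrac_s
          next
        }
      }
      vm[k] <- v
    }
    list(vm = vm, spikes = spikes)
  }
  withr::with_seed(seed, {
    trial_currents <- lapply(seq_len(2 * n_trials + 8), function(k) {
      base_i + stats::rnorm(length(base_i), 0, p$trial_noise_pa)
    })
    calib <- trial_currents[2 * n_trials + seq_len(8)]
    base_count <- mean(vapply(calib, function(i) length(run_lif(i, 0)$spikes),
                              numeric(1)))
    hyper <- 0
    if (inhibition_fraction > 0 && base_count > 0) {
      target <- base_count * (1 - inhibition_fraction)
      lo <- 0; hi <- 200
      for (it in 1:18) {
        mid <- (lo + hi) / 2
        cnt <- mean(vapply(calib, function(i) length(run_lif(i, mid)$spikes),
                           numeric(1)))
        if (cnt > target) lo <- mid else hi <- mid
      }
      hyper <- (lo + hi) / 2
    }
    out <- list()
    for (k in seq_len(n_trials)) {
      for (cond in c("no_light", "continuous_light")) {
        idx <- if (cond == "no_light") k else n_trials + k
        res <- run_lif(trial_currents[[idx]],
                       if (cond == "continuous_light") hyper else 0)
        out[[length(out) + 1]] <- structure(list(
          vm = cont_signal(res$vm, fs = fs, label = "Vm", units = "mV"),
          stim_current = current, light_ttl_times_s = numeric(0),
          condition = cond, spike_times_s = res$spikes
        ), class = "intracellular_sweep")
      }
    }
    out
  })
}
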