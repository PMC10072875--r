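#' Detect spike-and-wave discharges from a spectrogram
#'
#' Thresholds 7-10 Hz band power at an adaptive level (median + `threshold_k`
#' x MAD of the band-power trace, making detection invariant to overall
#' amplitude scaling), merges candidate intervals separated by gaps shorter
#' than `merge_gap_s`, and then applies the two inclusion rules: events must
#' last between `min_dur_s` and `max_dur_s` (2-30 s), and the spectrogram
#' frequency of maximum power inside the event must lie within the absence
#' band (7-10 Hz) — candidates peaking elsewhere are discarded.
#'
#' @param spec A `spectrogram` covering at least the detection band.
#' @param threshold_k MAD multiplier for the adaptive threshold (> 0,
#'   default 6).
#' @param min_dur_s,max_dur_s Duration limits in seconds (defaults 2 and 30).
#' @param band Length-2 detection band (Hz), default `c(7, 10)`.
#' @param merge_gap_s Gaps below this are merged before the duration rule.
#' @return A tibble of accepted events, sorted and non-overlapping:
#'   `start_s`, `end_s`, `duration_s`, `peak_freq_hz`, `peak_power`.
#' @export
detect_seizures <- function(spec, threshold_k = 6, min_dur_s = 2,
                            max_dur_s = 30, band = c(7, 10),
                            merge_gap_s = 0.5) {
  if (threshold_k <= 0) stop("threshold_k must be positive")
  if (min(spec$freqs_hz) > band[1] || max(spec$freqs_hz) < band[2]) {
    stop("spectrogram does not cover the detection band")
  }
  bp <- as.numeric(band_power(spec, band[1], band[2]))
  thr <- stats::median(bp) + threshold_k * stats::mad(bp)
  above <- bp > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- cbind(starts[runs$values], ends[runs$values])
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
    duration_s = numeric(0), peak_freq_hz = numeric(0), peak_power = numeric(0))
  if (nrow(cand) == 0 || is.null(nrow(cand))) return(empty)
  t <- spec$times_s
  dt <- stats::median(diff(t))
  # merge gaps shorter than merge_gap_s
  merged <- cand[1, , drop = FALSE]
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      gap <- (cand[i, 1] - merged[nrow(merged), 2]) * dt
      if (gap < merge_gap_s) {
        merged[nrow(merged), 2] <- cand[i, 2]
      } else {
        merged <- rbind(merged, cand[i, ])
      }
    }
  }
  out <- lapply(seq_len(nrow(merged)), function(i) {
    i0 <- merged[i, 1]; i1 <- merged[i, 2]
    dur <- (i1 - i0 + 1) * dt
    if (dur < min_dur_s || dur > max_dur_s) return(NULL)
    seg <- spec$power[, i0:i1, drop = FALSE]
    prof <- rowMeans(seg)
    pk_row <- which.max(prof)
    # sub-grid peak frequency by parabolic interpolation in log-frequency:
    # the raw argmax can only land on grid points, so a fundamental just
    # inside the band could otherwise be quantized to a point just outside it
    pk_freq <- spec$freqs_hz[pk_row]
    if (pk_row > 1 && pk_row < length(prof)) {
      lf <- log(spec$freqs_hz[(pk_row - 1):(pk_row + 1)])
      y <- prof[(pk_row - 1):(pk_row + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (denom < 0) {
        delta <- 0.5 * (y[1] - y[3]) / denom
        pk_freq <- exp(lf[2] + delta * (lf[3] - lf[1]) / 2)
      }
    }
    if (pk_freq < band[1] || pk_freq > band[2]) return(NULL)
    tibble::tibble(
      start_s = t[i0], end_s = t[i1] + dt, duration_s = dur,
      peak_freq_hz = pk_freq, peak_power = max(seg)
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$start_s)
}

#' Seizure rate normalized to session length
#'
#' @param events Event tibble from [detect_seizures()] (or anything with one
#'   row per event).
#' @param session_duration_s Session length in seconds (> 0).
#' @return Seizures per minute.
#' @export
seizure_rate <- function(events, session_duration_s) {
  if (session_duration_s <= 0) stop("session_duration_s must be positive")
  nrow(events) / (session_duration_s / 60)
}

#' Seizure-trial overlap summary
#'
#' Computes the percentage of initiated trials with a seizure during the cue
#' (event intersecting `[cue_on, cue_off)`) and within `margin_s` of the
#' trial. The margin window anchors on the full trial interval
#' (`[init - margin, end + margin]`, where end is the choice time or cue
#' offset) by default, or on the cue interval with `anchor = "cue"` — the
#' source text labels this measure both ways.
#'
#' @param events Event tibble (`start_s`, `end_s`).
#' @param session A [session_table] on the same time base.
#' @param margin_s Margin in seconds (default 10).
#' @param anchor "trial" or "cue".
#' @return A one-row tibble: `n_events`, `seizures_per_min`,
#'   `pct_trials_with_seizure_within_margin`, `pct_trials_with_seizure_during_cue`.
#' @export
trial_overlap <- function(events, session, margin_s = 10,
                          anchor = c("trial", "cue")) {
  anchor <- match.arg(anchor)
  n_tr <- nrow(session)
  intersects <- function(lo, hi) {
    if (nrow(events) == 0) return(FALSE)
    any(events$start_s < hi & events$end_s > lo)
  }
  during_cue <- vapply(seq_len(n_tr), function(i) {
    intersects(session$cue_on_s[i], session$cue_off_s[i])
  }, logical(1))
  within_margin <- vapply(seq_len(n_tr), function(i) {
    if (anchor == "trial") {
      lo <- session$init_time_s[i]
      hi <- ifelse(is.na(session$choice_time_s[i]),
                   session$cue_off_s[i], session$choice_time_s[i])
    } else {
      lo <- session$cue_on_s[i]
      hi <- session$cue_off_s[i]
    }
    intersects(lo - margin_s, hi + margin_s)
  }, logical(1))
  tibble::tibble(
    n_events = nrow(events),
    seizures_per_min = seizure_rate(events, session_duration(session)),
    pct_trials_with_seizure_within_margin = 100 * mean(within_margin),
    pct_trials_with_seizure_during_cue = 100 * mean(during_cue)
  )
}

#' Match detected seizures against generator ground truth
#'
#' A detection matches a true event when the intervals overlap. Used to score
#' the detector on synthetic recordings.
#'
#' @param detected,truth Event tibbles with `start_s` / `end_s`.
#' @return A one-row tibble: `n_true`, `n_detected`, `tp`, `sensitivity`,
#'   `precision`.
#' @export
score_detection <- function(detected, truth) {
  overlap <- function(a0, a1, b0, b1) a0 < b1 & a1 > b0
  tp_true <- vapply(seq_len(nrow(truth)), function(i) {
    nrow(detected) > 0 && any(overlap(detected$start_s, detected$end_s,
                                      truth$start_s[i], truth$end_s[i]))
  }, logical(1))
  tp_det <- vapply(seq_len(nrow(detected)), function(i) {
    nrow(truth) > 0 && any(overlap(truth$start_s, truth$end_s,
                                   detected$start_s[i], detected$end_s[i]))
  }, logical(1))
  tibble::tibble(
    n_true = nrow(truth), n_detected = nrow(detected), tp = sum(tp_true),
    sensitivity = if (nrow(truth) == 0) NA_real_ else mean(tp_true),
    precision = if (nrow(detected) == 0) NA_real_ else mean(tp_det)
  )
}
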