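#' Threshold-crossing spike detection
#'
#' Upward crossings of a voltage threshold, with at most one spike per
#' refractory window.
#'
#' @param vm A [cont_signal] in mV.
#' @param threshold_mv Detection threshold (default 0 mV).
#' @param refractory_s Minimum inter-spike interval (default 2 ms).
#' @return Numeric vector of spike times (s).
#' @export
detect_spikes <- function(vm, threshold_mv = 0, refractory_s = 0.002) {
  x <- as.numeric(vm)
  up <- which(x[-1] >= threshold_mv & x[-length(x)] < threshold_mv) + 1
  t <- signal_times(vm)[up]
  if (length(t) <= 1) return(t)
  keep <- rep(TRUE, length(t))
  last <- t[1]
  for (i in 2:length(t)) {
    if (t[i] - last < refractory_s) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

#' Percent spike reduction under optogenetic inhibition
#'
#' `100 * (mean_no_light - mean_light) / mean_no_light`, comparing spike
#' counts within cells between no-light and light conditions. The alternative
#' reading of the source formula (light-count denominator) is attached as
#' attribute `alt_light_denominator`.
#'
#' @param no_light_counts,light_counts Spike counts per sweep.
#' @return Percent reduction (scalar). `NA` with a warning if no spikes occur
#'   without light.
#' @export
spike_reduction <- function(no_light_counts, light_counts) {
  m0 <- mean(no_light_counts)
  m1 <- mean(light_counts)
  if (m0 == 0) {
    warning("no spikes in the no-light condition; reduction undefined")
    return(NA_real_)
  }
  out <- 100 * (m0 - m1) / m0
  attr(out, "alt_light_denominator") <- if (m1 > 0) 100 * (m0 - m1) / m1 else NA_real_
  out
}

#' Last-bin spike and membrane-potential metrics
#'
#' Sustained-inhibition measure for continuous-light sweeps: spike count and
#' mean Vm over the final 0.5 s of the light window, against mean Vm over the
#' 0.5 s immediately before light onset (baseline). If the light window is
#' shorter than 0.5 s the full window is used and flagged.
#'
#' @param sweep An `intracellular_sweep` (list with `vm` and optionally
#'   `spike_times_s`).
#' @param light_on_s,light_len_s Light window (s), within the sweep.
#' @param spike_threshold_mv,refractory_s Passed to [detect_spikes()] when the
#'   sweep carries no precomputed spike times.
#' @return A one-row tibble: `last_bin_count`, `mean_vm_last_bin_mv`,
#'   `mean_vm_baseline_mv`, `delta_vm_mv`, `bin_s`, `short_window`.
#' @export
last_bin_metrics <- function(sweep, light_on_s, light_len_s,
                             spike_threshold_mv = 0, refractory_s = 0.002) {
  vm <- sweep$vm
  t_end <- signal_t0(vm) + signal_duration(vm)
  if (light_on_s < signal_t0(vm) || light_on_s + light_len_s > t_end) {
    stop("light interval outside the sweep")
  }
  short <- light_len_s < 0.5
  if (short) warning("light window shorter than 0.5 s; using the full window")
  bin <- if (short) light_len_s else 0.5
  bin_lo <- light_on_s + light_len_s - bin
  bin_hi <- light_on_s + light_len_s
  spikes <- if (!is.null(sweep$spike_times_s)) sweep$spike_times_s
    else detect_spikes(vm, spike_threshold_mv, refractory_s)
  tibble::tibble(
    last_bin_count = sum(spikes >= bin_lo & spikes < bin_hi),
    mean_vm_last_bin_mv = mean(signal_window(vm, bin_lo, bin_hi)),
    mean_vm_baseline_mv = mean(signal_window(vm, light_on_s - 0.5, light_on_s)),
    delta_vm_mv = mean(signal_window(vm, bin_lo, bin_hi)) -
      mean(signal_window(vm, light_on_s - 0.5, light_on_s)),
    bin_s = bin, short_window = short
  )
}

#' IPSP failure analysis over a 40 Hz light train
#'
#' Aligns the membrane potential to each TTL pulse, takes the mean of the
#' 2 ms immediately preceding the pulse as baseline, and measures the peak
#' deflection (extremum of Vm - baseline, either polarity) within a 0.025 s
#' half-open window from the pulse. Responses with |deflection| below
#' `failure_threshold_mv` (default 0.25 mV) count as failures. Per-sweep
#' failure percentages are averaged across sweeps for the per-cell value. At
#' 40 Hz the 25 ms windows exactly abut; TTL spacing below the window is an
#' error.
#'
#' @param sweeps A list of `intracellular_sweep`s (each with `vm` and
#'   `light_ttl_times_s`), or a single sweep.
#' @param failure_threshold_mv Failure criterion on |peak deflection|.
#' @param window_s Response window after each pulse (default 0.025 s).
#' @return A tibble, one row per sweep: `sweep`, `n_pulses`, `n_failures`,
#'   `failure_pct`, with the across-sweep mean attached as attribute
#'   `cell_mean_pct` (also via [failure_rate()]). Per-pulse deflections are in
#'   attribute `pulses` (tibble: sweep, pulse, deflection_mv, is_failure).
#' @export
ipsp_failures <- function(sweeps, failure_threshold_mv = 0.25,
                          window_s = 0.025) {
  if (inherits(sweeps, "intracellular_sweep")) sweeps <- list(sweeps)
  per_sweep <- list()
  per_pulse <- list()
  for (k in seq_along(sweeps)) {
    sw <- sweeps[[k]]
    ttl <- sort(sw$light_ttl_times_s)
    if (length(ttl) < 1) stop("sweep ", k, " has no TTL pulses")
    if (length(ttl) > 1 && any(diff(ttl) < window_s - 1e-9)) {
      stop("TTL spacing shorter than the response window")
    }
    vm <- sw$vm
    defl <- vapply(ttl, function(tt) {
      base <- mean(signal_window(vm, tt - 0.002, tt))
      seg <- signal_window(vm, tt, tt + window_s) - base
      seg[which.max(abs(seg))]
    }, numeric(1))
    fail <- abs(defl) < failure_threshold_mv
    per_sweep[[k]] <- tibble::tibble(
      sweep = k, n_pulses = length(ttl), n_failures = sum(fail),
      failure_pct = 100 * mean(fail)
    )
    per_pulse[[k]] <- tibble::tibble(sweep = k, pulse = seq_along(ttl),
      deflection_mv = defl, is_failure = fail)
  }
  out <- dplyr::bind_rows(per_sweep)
  attr(out, "cell_mean_pct") <- mean(out$failure_pct)
  attr(out, "pulses") <- dplyr::bind_rows(per_pulse)
  out
}

#' @rdname ipsp_failures
#' @param report A tibble from [ipsp_failures()].
#' @return `failure_rate()`: the per-cell mean failure percentage.
#' @export
failure_rate <- function(report) attr(report, "cell_mean_pct")
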