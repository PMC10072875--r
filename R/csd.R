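#' Current source density from a laminar LFP sweep
#'
#' The CSD is the negated second spatial derivative of the local field
#' potential across equally spaced laminar channels:
#' `CSD_i(t) = -(V[i-1](t) - 2 V[i](t) + V[i+1](t)) / h^2`, with the
#' electrode spacing `h` in mm, so values carry units V/mm^2. Net inward
#' membrane current (a sink, extracellular negativity) appears negative,
#' sources positive. Edge channels, where the second difference is
#' undefined, are dropped (no padding).
#'
#' @param sweep A channel x time numeric matrix (>= 3 channels), volts.
#' @param spacing_um Inter-electrode spacing in micrometers (> 0).
#' @param fs Sampling rate (Hz), carried through for the time axis.
#' @param t0 Time of the first sample (s).
#' @return An object of class `csd_map`: `values`
#'   ((n_channels - 2) x time, V/mm^2), `channels` (the interior channel
#'   indices), `channel_depths_um`, `times_s`, `n` (sweeps averaged, 1 here).
#' @export
compute_csd <- function(sweep, spacing_um = 100, fs = 25000, t0 = 0) {
  sweep <- as.matrix(sweep)
  n_ch <- nrow(sweep)
  if (n_ch < 3) stop("CSD needs at least 3 channels")
  if (spacing_um <= 0) stop("spacing_um must be positive")
  h_mm <- spacing_um / 1000
  interior <- 2:(n_ch - 1)
  vals <- -(sweep[interior - 1, , drop = FALSE] -
            2 * sweep[interior, , drop = FALSE] +
            sweep[interior + 1, , drop = FALSE]) / h_mm^2
  structure(list(
    values = vals, channels = interior,
    channel_depths_um = (interior - 1) * spacing_um,
    times_s = t0 + (seq_len(ncol(sweep)) - 1) / fs, n = 1L
  ), class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map> %d interior channels x %d samples (n = %d sweeps)\n",
    nrow(x$values), ncol(x$values), x$n))
  invisible(x)
}

#' @export
as_tibble.csd_map <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$times_s, each = nrow(x$values)),
    channel = rep(x$channels, times = ncol(x$values)),
    depth_um = rep(x$channel_depths_um, times = ncol(x$values)),
    csd = as.numeric(x$values)
  )
}

#' Trial-average CSD maps by group
#'
#' Element-wise mean of same-shaped CSD maps within each group (typically
#' stimulation intensity; the source protocol averages 10 trials per
#' intensity).
#'
#' @param maps A list of `csd_map` objects of identical shape.
#' @param group A vector (length = number of maps) of group keys, e.g.
#'   stimulation intensities in uA. Default: one group.
#' @return A named list of averaged `csd_map`s, one per group, each with `n`
#'   set to the number of sweeps averaged.
#' @export
csd_trial_average <- function(maps, group = rep(1, length(maps))) {
  stopifnot(length(maps) == length(group))
  shapes <- vapply(maps, function(m) paste(dim(m$values), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1) stop("maps have mixed shapes: ",
    paste(unique(shapes), collapse = ", "))
  out <- lapply(split(seq_along(maps), group), function(idx) {
    avg <- maps[[idx[1]]]
    avg$values <- Reduce(`+`, lapply(maps[idx], `[[`, "values")) / length(idx)
    avg$n <- length(idx)
    avg
  })
  out
}

#' Signed peak amplitude of a CSD component
#'
#' Within a named channel x latency window, a sink component's amplitude is
#' the minimum CSD value (sinks are negative) and a source component's is the
#' maximum. If the extremum's sign contradicts the declared component sign,
#' the value is still returned with a `sign_mismatch` warning flag.
#'
#' @param map A `csd_map`.
#' @param channels Channel indices (matching `map$channels`) of the window.
#' @param t_lo,t_hi Latency window in seconds (half-open).
#' @param sign "sink" or "source".
#' @return A one-row tibble: `amplitude` (signed, V/mm^2), `channel`,
#'   `time_s` of the extremum, `sign_mismatch`.
#' @export
component_amplitude <- function(map, channels, t_lo, t_hi,
                                sign = c("sink", "source")) {
  sign <- match.arg(sign)
  rows <- match(channels, map$channels)
  if (anyNA(rows)) stop("window channels outside the map interior")
  cols <- which(map$times_s >= t_lo & map$times_s < t_hi)
  if (length(cols) == 0) stop("latency window outside the map")
  seg <- map$values[rows, cols, drop = FALSE]
  idx <- if (sign == "sink") which.min(seg) else which.max(seg)
  val <- seg[idx]
  mismatch <- (sign == "sink" && val > 0) || (sign == "source" && val < 0)
  if (mismatch) warning("component extremum sign contradicts '", sign, "' window")
  rc <- arrayInd(idx, dim(seg))
  tibble::tibble(
    amplitude = val, channel = channels[rc[1]],
    time_s = map$times_s[cols[rc[2]]], sign_mismatch = mismatch
  )
}

#' Component amplitude versus stimulation intensity
#'
#' Runs [compute_csd()] on every sweep of a `laminar_sweep_set`, trial-averages
#' within intensity, and extracts one signed component amplitude per
#' intensity.
#'
#' @param sweep_set A `laminar_sweep_set` from [gen_laminar()] (or the same
#'   structure built from real data).
#' @param channels,t_lo,t_hi,sign Component window; see
#'   [component_amplitude()]. Defaults: the sink channel band around the
#'   injected geometry over 2-40 ms post-stimulus.
#' @return A tibble: `stim_intensity_uA`, `amplitude`, `n_trials`, sorted by
#'   intensity.
#' @export
amplitude_curve <- function(sweep_set, channels, t_lo = NULL, t_hi = NULL,
                            sign = "sink") {
  if (is.null(t_lo)) t_lo <- sweep_set$stim_onset_s + 0.002
  if (is.null(t_hi)) t_hi <- sweep_set$stim_onset_s + 0.04
  maps <- lapply(sweep_set$sweeps, compute_csd,
                 spacing_um = sweep_set$spacing_um, fs = sweep_set$fs)
  avg <- csd_trial_average(maps, group = sweep_set$stim_intensity_uA)
  purrr::map_dfr(names(avg), function(g) {
    amp <- component_amplitude(avg[[g]], channels, t_lo, t_hi, sign)
    tibble::tibble(stim_intensity_uA = as.numeric(g),
                   amplitude = amp$amplitude, n_trials = avg[[g]]$n)
  }) |> dplyr::arrange(.data$stim_intensity_uA)
}
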