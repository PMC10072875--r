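#' Run the full synthetic demo pipeline
#'
#' Executes every analysis stage on synthetic data in dependency order:
#' ECoG simulation -> spectrogram -> seizure detection and trial overlap;
#' session simulation -> behavioral scoring; photometry simulation ->
#' motion correction, dF/F, trial features -> outcome decoding with a
#' shuffled-label null; laminar simulation -> CSD amplitude curves; IPSP
#' trains -> failure rates; noisy-current spiking -> spike reduction. All
#' randomness derives from the single `seed` through a counter-based
#' child-seed scheme, so identical config + seed gives byte-identical
#' outputs; the run manifest records the config, seeds and an MD5 hash of
#' every file written.
#'
#' @param config An `analysis_config` (see [load_analysis_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed (overrides `config$seed` if given).
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` alongside the outputs.
#' @export
run_pipeline <- function(config = load_analysis_config(), out_dir, seed = NULL) {
  if (is.null(seed)) seed <- config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  outputs <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    outputs <<- c(outputs, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  # --- ECoG -> seizures ---------------------------------------------------
  ec <- gen_ecog(sim$ecog$duration_s, sim$ecog$fs,
                 sim$ecog$swd_rate_per_min,
                 swd_params = list(amp_rel = sim$ecog$swd_amp_rel),
                 seed = child_seed(seed, 1))
  dec <- decimate_signal(ec$signal, config$spectral$decimate_to_hz)
  freqs <- exp(seq(log(config$spectral$f_min_hz),
                   log(min(config$spectral$f_max_hz,
                           0.45 * config$spectral$decimate_to_hz)),
                   length.out = config$spectral$n_voices))
  spec <- morlet_cwt(dec, freqs_hz = freqs, omega0 = config$spectral$omega0)
  events <- detect_seizures(spec,
    threshold_k = config$seizure$threshold_k,
    min_dur_s = config$seizure$min_dur_s, max_dur_s = config$seizure$max_dur_s,
    band = config$seizure$band, merge_gap_s = config$seizure$merge_gap_s)
  emit_csv(events, "seizure_events.csv")
  emit_csv(score_detection(events, ec$truth), "seizure_detection_score.csv")
  emit_json(list(rate_per_min = seizure_rate(events, sim$ecog$duration_s)),
            "seizure_rate.json")

  # --- behavior ------------------------------------------------------------
  session <- gen_session(sim$session$n_trials, sim$session$task,
                         sim$session$cue_lengths, seed = child_seed(seed, 2))
  beh <- behavior_summary(session, rt_anchor = config$behavior$rt_anchor)
  emit_csv(beh$by_cue, "behavior_by_cue.csv")
  emit_csv(beh$session, "behavior_session.csv")
  emit_csv(trial_overlap(events, session, margin_s = config$seizure$margin_s,
                         anchor = config$seizure$margin_anchor),
           "seizure_trial_overlap.csv")

  # --- photometry -> decoding ---------------------------------------------
  # correct trials carry larger cue-locked transients so outcome is decodable
  amp <- ifelse(session$outcome == "correct", 0.08, 0.03)
  truth <- tibble::tibble(amp = amp, latency_s = 0.2, rise_tau_s = 0.15,
                          decay_tau_s = 0.6)
  rec <- gen_photometry(session, truth,
                        motion_scale = sim$photometry$motion_scale,
                        noise_sd = sim$photometry$noise_sd,
                        fs = sim$photometry$fs, seed = child_seed(seed, 3))
  phot <- process_photometry(rec, session,
                             pre_s = config$photometry$pre_s,
                             post_s = config$photometry$post_s)
  emit_csv(phot$features, "photometry_features.csv")
  feat <- phot$features |>
    dplyr::filter(.data$outcome != "omission") |>
    dplyr::mutate(label = .data$outcome)
  feat <- normalize_features(feat)
  dcfg <- config$decoding
  report <- crossval_auc(feat, k = dcfg$k_folds, repeats = dcfg$repeats,
    row_subsample = dcfg$row_subsample, col_subsample = dcfg$col_subsample,
    max_depth = dcfg$max_depth, nrounds = dcfg$nrounds, eta = dcfg$eta,
    k_neighbors = dcfg$k_neighbors, seed = child_seed(seed, 4))
  report <- null_model(feat, report, k_neighbors = dcfg$k_neighbors,
                       seed = child_seed(seed, 5))
  emit_json(list(mean_auc = report$mean_auc,
                 null_mean_auc = report$null$null_mean_auc,
                 p_value = report$null$p_value,
                 fold_aucs = report$fold_aucs$auc,
                 null_fold_aucs = report$null$null_fold_aucs$auc),
            "decoding_report.json")

  # --- laminar CSD ---------------------------------------------------------
  lam <- gen_laminar(sim$laminar$sink_channel,
                     amplitude_per_intensity = 1:5,
                     n_trials = sim$laminar$n_trials_per_intensity,
                     noise_sd = sim$laminar$noise_sd,
                     seed = child_seed(seed, 6))
  curve <- amplitude_curve(lam,
    channels = sim$laminar$sink_channel + (-1:1), sign = "sink")
  emit_csv(curve, "csd_amplitude_curve.csv")

  # --- intracellular -------------------------------------------------------
  ipsp <- gen_ipsp_sweeps(sim$ipsp$n_trials, sim$ipsp$p_release,
                          sim$ipsp$ipsp_amp_mv,
                          noise_sd_mv = sim$ipsp$noise_sd_mv,
                          seed = child_seed(seed, 7))
  fr <- ipsp_failures(ipsp,
    failure_threshold_mv = config$intracellular$failure_threshold_mv,
    window_s = config$intracellular$response_window_s)
  emit_csv(fr, "ipsp_failures.csv")
  emit_json(list(cell_mean_failure_pct = failure_rate(fr)), "ipsp_summary.json")

  cur <- gen_noisy_current(0.5, 10000, seed = child_seed(seed, 8))
  sweeps <- gen_spike_sweeps(cur, sim$spikes$inhibition_fraction,
                             n_trials = sim$spikes$n_trials,
                             seed = child_seed(seed, 9))
  counts <- vapply(sweeps, function(s) length(s$spike_times_s), numeric(1))
  cond <- vapply(sweeps, function(s) s$condition, character(1))
  red <- spike_reduction(counts[cond == "no_light"],
                         counts[cond == "continuous_light"])
  emit_json(list(spike_reduction_pct = as.numeric(red)),
            "spike_reduction.json")

  manifest <- list(
    seed = seed,
    config = unclass(config),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

#' Collect pipeline outputs into summary tables
#'
#' Reads the per-stage outputs of [run_pipeline()] back into a named list of
#' tibbles — the per-figure-style summaries (behavioral accuracy, seizure
#' rate and overlap, photometry features, CSD amplitude curve, failure rates,
#' decoding AUCs). Regeneration is idempotent.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return A named list of tibbles/lists, one per stage output present;
#'   missing stages are omitted with a message.
#' @export
pipeline_report <- function(out_dir) {
  want <- c(
    behavior_by_cue = "behavior_by_cue.csv",
    behavior_session = "behavior_session.csv",
    seizure_events = "seizure_events.csv",
    seizure_trial_overlap = "seizure_trial_overlap.csv",
    photometry_features = "photometry_features.csv",
    csd_amplitude_curve = "csd_amplitude_curve.csv",
    ipsp_failures = "ipsp_failures.csv"
  )
  out <- list()
  for (nm in names(want)) {
    p <- file.path(out_dir, want[[nm]])
    if (file.exists(p)) {
      out[[nm]] <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    } else {
      message("stage output missing, omitted: ", want[[nm]])
    }
  }
  for (nm in c("seizure_rate", "decoding_report", "ipsp_summary",
               "spike_reduction")) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    if (file.exists(p)) out[[nm]] <- jsonlite::read_json(p)
  }
  out
}
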