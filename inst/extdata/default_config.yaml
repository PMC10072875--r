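# Default analysis configuration. Every pipeline stage reads its parameter
# group from here; values are validated against documented ranges at load time.
seed: 1
spectral:
  omega0: 6            # Morlet center frequency (cycles)
  f_min_hz: 1
  f_max_hz: 100
  n_voices: 48         # log-spaced frequency grid points
  decimate_to_hz: 200  # anti-aliased decimation before CWT (content < 100 Hz)
  normalize: peak_log10
bands:
  theta: [7, 10]       # SWD fundamental (modified-theta band)
  beta: [10, 20]       # second harmonic
  b4_8: [4, 8]
  b8_12: [8, 12]
  b12_30: [12, 30]
  b30_50: [30, 50]     # low gamma
  b60_90: [60, 90]     # high gamma
seizure:
  threshold_k: 6       # median + k*MAD adaptive threshold on 7-10 Hz power
  min_dur_s: 2
  max_dur_s: 30
  merge_gap_s: 0.5
  band: [7, 10]
  margin_s: 10
  margin_anchor: trial # trial | cue
photometry:
  pre_s: 1
  post_s: 5
  baseline_s: 1        # the second immediately prior to the cue
intracellular:
  failure_threshold_mv: 0.25
  response_window_s: 0.025
  spike_threshold_mv: 0
  refractory_s: 0.002
  last_bin_s: 0.5
behavior:
  omission_limit_s: 5
  rt_anchor: cue_off   # cue_off | init
  engagement_rate_per_min: 1
  repetitive_mode: disjoint  # disjoint | sliding
csd:
  spacing_um: 100
decoding:
  outlier_factor: 10
  k_neighbors: 5
  k_folds: 10
  repeats: 3
  row_subsample: 0.8
  col_subsample: 0.3
  max_depth: 3
  nrounds: 200
  eta: 0.1
simulate:
  ecog:
    duration_s: 600
    fs: 1000
    swd_rate_per_min: 0.3
    swd_amp_rel: 5     # event RMS relative to background RMS
  session:
    n_trials: 60
    task: AET
    cue_lengths: [5, 2, 0.5]
  photometry:
    fs: 20
    transient_amp: 0.05
    motion_scale: 0.5
    noise_sd: 0.005
  laminar:
    sink_channel: 8
    n_trials_per_intensity: 10
    noise_sd: 1.0e-4   # ~0.1 mV LFP noise on mV-scale evoked responses
  ipsp:
    n_trials: 5
    p_release: 0.8
    ipsp_amp_mv: 1.0
    noise_sd_mv: 0.05
  spikes:
    inhibition_fraction: 0.5
    n_trials: 5
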