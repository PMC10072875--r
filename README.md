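# attnephys

Analysis of attention-task electrophysiology, fiber photometry and behavior
in an absence-epilepsy mouse model.

## The problem

Absence epilepsy is marked by spike-and-wave discharges (SWDs) — rhythmic
7–10 Hz cortical oscillations with a prominent second harmonic — and by
attention deficits that persist between seizures. Linking the two requires a
stack of signal-analysis stages that are usually scattered across ad-hoc lab
scripts: detecting SWDs in ECoG, quantifying band-limited oscillatory power
around task events, extracting cue-locked calcium transients from
parvalbumin-interneuron fiber photometry, mapping evoked current sinks and
sources across cortical laminae, scoring inhibitory synaptic failures and
optogenetic spike suppression in slice recordings, scoring a cue-length-varied
two-port attention task, and finally decoding trial outcome from per-trial
photometry features.

`attnephys` implements that full stack as a tested, seed-reproducible R
package, together with a synthetic-data module that generates every input
class with known ground truth — so each analysis stage can be validated
end-to-end without animal data.

## The methods at its core

- **Spectral**: Morlet continuous-wavelet spectrograms (ω₀ = 6,
  log-spaced frequency grid), band power for the SWD fundamental
  Ø (7–10 Hz) / harmonic β (10–20 Hz) pair and the 4–8 / 8–12 / 12–30 /
  30–50 / 60–90 Hz set, peak-normalized log₁₀ power, event-aligned means and
  variances.
- **Seizure detection**: adaptive thresholding of 7–10 Hz band power at
  median + k·MAD (k = 6), gap merging, the 2–30 s duration rule and the
  7–10 Hz peak-frequency rule; rates as seizures/min and trial-overlap
  percentages.
- **Photometry**: least-squares isosbestic (405 nm) motion correction,
  dF/F = (f − median f)/median f, cue-aligned trial matrices with a fixed
  1 s pre-cue baseline, and per-trial features (baseline/cue means, peak,
  time-to-peak, plus 22 summary-statistic decoding features).
- **CSD**: current source density as the negated second spatial derivative
  of 16-channel laminar LFPs (100 µm spacing, V/mm², sinks negative),
  trial-averaged component amplitude curves versus stimulation intensity.
- **Intracellular**: threshold spike detection, percent spike reduction
  100·(n_noLight − n_light)/n_noLight, last-0.5 s window metrics, and 40 Hz
  IPSP-train failure rates (|deflection| < 0.25 mV within 25 ms of each TTL).
- **Behavior**: accuracy by cue length over responded trials, the 5 s
  omission rule, both reaction-time definitions, disjoint blocks-of-five
  repetitive-responding score, the 70%×3-day / 90%×2-day training criterion,
  and the 1 trial/min engagement filter.
- **Decoding**: 10×-SD outlier removal, min/max feature normalization
  (raw extremes exempt), SMOTE + Tomek-link rebalancing to a near 50:50
  class balance applied inside training folds only, gradient-boosted trees
  (depth 3, 200 rounds, η = 0.1, 80% row / 30% feature subsampling) under
  repeated (k = 10, n = 3) stratified cross-validation, and a
  shuffled-label null with a rank-sum comparison.

Everything is tidyverse-shaped: functions take data frames first and return
tibbles, fitted decoding reports have `tidy()`/`glance()` methods, and every
result type has an `autoplot()`.

## Worked example

Simulate a 10-minute ECoG with SWDs at 0.5/min, detect them, and score a
synthetic attention-task session:

```r
library(attnephys)

g <- gen_ecog(duration_s = 600, fs = 1000, swd_rate_per_min = 0.5, seed = 11)
spec <- morlet_cwt(decimate_signal(g$signal, 200),
                   freqs_hz = exp(seq(log(2), log(80), length.out = 40)))
events <- detect_seizures(spec, threshold_k = 6)
events
#> # A tibble: 4 × 5
#>   start_s end_s duration_s peak_freq_hz peak_power
#>     <dbl> <dbl>      <dbl>        <dbl>      <dbl>
#> 1    96.5  101.       4.46         7.72 0.00000877
#> 2   111.   117.       5.44         7.42 0.00000983
#> 3   325.   331.       6.74         7.07 0.0000102
#> 4   571.   580.       8.74         7.96 0.00000927
seizure_rate(events, 600)
#> [1] 0.4
```

Four events were detected (the generator injected four), each 4.5–8.7 s long
with its spectral peak inside the 7–10 Hz absence band, giving 0.4
seizures/min. Behavioral scoring from a generated session:

```r
session <- gen_session(60, cue_lengths = c(5, 2, 0.5),
  psycho = list(p_correct = list(`5` = 0.9, `2` = 0.75, `0.5` = 0.6),
                p_omit = 0.05), seed = 7)
score_accuracy(session)
#> # A tibble: 3 × 7
#>   cue_length_s n_trials n_responded n_correct n_omissions pct_correct
#>          <dbl>    <int>       <int>     <int>       <int>       <dbl>
#> 1          5         20          20        18           0        90
#> 2          2         20          17        12           3        70.6
#> 3          0.5       20          19        11           1        57.9
```

Accuracy is computed over responded trials only (omissions are a separate
column) and falls with cue length, mirroring the programmed psychometric
profile. `run_pipeline(load_analysis_config(), out_dir, seed)` chains every
stage — simulation, detection, photometry features, decoding with its null,
CSD curves, failure rates — and writes a hash-stamped run manifest.

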