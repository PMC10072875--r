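---
title: "Methods and design choices in attnephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in attnephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`attnephys` re-implements, as one coherent package, the analysis stack used
to relate prefrontal parvalbumin-interneuron (PVIN) activity and cortical
oscillations to attention performance in an absence-epilepsy mouse model.
This vignette explains each stage's model and assumptions, the parameters
that matter, what the synthetic-data generators emulate (and deliberately do
not), and the numerical choices made where the design was genuinely open.

## Time conventions

All times are seconds from session start, stored as 64-bit doubles. Sample
indexing is 0-based in time (sample *i* of a trace sits at `t0 + i/fs`), and
every analysis window is half-open `[start, end)`: a sample at exactly the
window end belongs to the next window. The signal container on disk is raw
little-endian float64 plus a JSON sidecar, which round-trips bit-exactly and
stays readable from any language.

## Spectral analysis

Spectrograms use the continuous wavelet transform with an analytic Morlet
mother wavelet. The center frequency is ω₀ = 6 — the common default that
balances time against frequency resolution (about one octave of full-width
frequency smear at ±2σ) — and the default grid is 48 log-spaced frequencies
over 1–100 Hz. Both are configuration, not constants: the analyses only need
the SWD fundamental Ø (7–10 Hz), its harmonic β (10–20 Hz), and the broader
4–8 / 8–12 / 12–30 / 30–50 / 60–90 Hz set.

Input ECoG is decimated to 1 kHz or below (zero-phase Butterworth at 80% of
the target Nyquist, then subsampling) before the transform; nothing above
100 Hz carries signal here, and the transform cost scales with the sample
count. "Normalized to peak" is interpreted as division by the *single global
maximum* of the spectrogram before the log₁₀ transform — so the normalized
log spectrogram has maximum exactly 0 — with a per-frequency variant behind
the `per_freq` flag. Cone-of-influence extents are reported per frequency
(`coi_s`) but contaminated edge samples are retained, not blanked; alignment
tests average away from edges instead.

## Seizure detection

The detector thresholds 7–10 Hz band power at median + k·MAD with k = 6.
The source method states no numeric threshold; an adaptive, robust threshold
was chosen because it makes detection invariant to overall amplitude scaling
(electrode impedance, amplifier gain), which is asserted in the tests.
Candidate intervals separated by less than 0.5 s are merged first — SWDs wax
and wane and would otherwise fragment — then two inclusion rules apply:
duration within 2–30 s, and the spectral peak inside the event must lie in
7–10 Hz. The peak frequency is refined by parabolic interpolation across the
log-frequency grid around the argmax row; without it a fundamental just
inside the band can be quantized onto the nearest grid point just outside
it and spuriously discarded.

"Trials with a seizure within 10 s" anchors the ±10 s margin on the full
trial interval (initiation to choice) by default; the narrower cue-interval
anchor is one configuration flag away, since the source describes the
measure both ways.

## Fiber photometry

The 405 nm isosbestic channel is scaled to the 470 nm channel by ordinary
least squares and subtracted; the 470 mean is then restored so that the
subsequent median normalization stays well defined (the source's order of
operations leaves the post-subtraction baseline unspecified). dF/F is
`(f − median f)/median f` with the median over the whole session — a single
session-wide median matches the stated procedure; a sliding variant would be
a detrending choice the source does not make. dF/F is invariant to
multiplicative gain of the raw channel, and a non-positive median is treated
as an upstream error rather than silently producing nonsense.

Trials are aligned to cue onset with a fixed `[-1, 0)` s baseline (the second
immediately before the cue) and a `[0, cue length)` cue window. Per-trial
features include two peak readouts. `peak_amplitude` is the raw cue-window
maximum minus the baseline mean — exact on noise-free traces, but biased
upward under wideband noise, because the expected maximum of *n* noise
samples grows like σ·√(2 ln n); at 20 Hz over a 5 s cue this bias reaches
tens of percent near detection threshold. `peak_smoothed` takes the maximum
on a 0.25 s zero-phase moving average first: GCaMP6s-speed transients
(≈0.15 s rise, ≈0.6 s decay) pass essentially unattenuated while the noise
maximum shrinks, and amplitude recovery on synthetic sweeps is unbiased
within a few percent once the transient exceeds about three times the dF/F
noise floor. The smoothed readout is what the recovery validation uses;
both are reported.

## Current source density

CSD is the negated second spatial difference of the laminar LFP,
`-(V[i-1] - 2V[i] + V[i+1])/h²` with h = 0.1 mm, in V/mm² — no conductivity
scaling, matching how such maps are usually plotted — with sinks negative.
Edge channels are dropped rather than padded (the quantified components are
interior), and no inverse-CSD methods are attempted. Component windows
(channel range × latency × expected sign) are configuration: the source
marks components graphically, not numerically, so defaults (early 2–10 ms
sinks, later source) are placeholders to be overridden per preparation.
Because the synthetic laminar generator builds LFPs by integrating a known
CSD profile twice across depth (plus free linear terms), the analysis is
validated as an exact inverse at zero noise.

## Intracellular metrics

Spike detection is upward threshold crossing (default 0 mV) with a 2 ms
refractory window — both unstated in the source and exposed as parameters.
Percent spike reduction uses the no-light count as denominator: the source
formula's precedence is ambiguous, but a reduction bounded by 100% implies
the no-light denominator; the light-denominator variant is attached as an
attribute. IPSP failure analysis aligns to each 40 Hz TTL, takes the mean of
the 2 ms immediately pre-pulse as baseline (the shortest window robust to
the previous IPSP's decay at 25 ms spacing), measures the absolute extremal
deflection within `[ttl, ttl + 25 ms)`, and calls |deflection| < 0.25 mV a
failure. The absolute value makes the result independent of IPSP polarity
at rest. At 40 Hz the response windows exactly abut; narrower spacing is an
error.

## Behavior

Accuracy is correct/(correct + incorrect) per cue length; omissions — no
choice, or a choice later than 5 s after cue termination — are excluded from
that denominator and reported separately. Repetitive responding counts
*disjoint* blocks of five consecutive same-port choices (each maximal run of
length L contributes ⌊L/5⌋), normalized by responded trials; a
sliding-window variant is available because the source phrasing admits both
readings. Reaction time defaults to the cue-termination anchor, with the
initiation anchor selectable — the source uses both definitions in different
places, and neither is asserted as canonical. The training criterion is the
earliest day ending 3 consecutive days ≥70% or 2 consecutive days ≥90%;
engagement requires ≥1 initiated trial per minute.

## Outcome decoding

Per-trial feature vectors are 11 summary statistics (mean, median, SD, min,
max, range, skewness, kurtosis, linear slope, integral, time-to-peak) over
each of the baseline and cue windows — 22 columns. The source names only
"simple summary statistics"; this list is fixed here and config-overridable.
Trials whose trace SD exceeds 10× the group mean SD are dropped (strict
inequality). All features except the raw trace extremes are min/max
normalized to [0, 1].

Class rebalancing is SMOTE (synthetic minority samples interpolated at a
uniform random fraction toward one of k = 5 Euclidean nearest minority
neighbours) followed by Tomek-link cleaning (the majority member of every
cross-class mutual-nearest-neighbour pair is removed), reaching a near
50:50 balance. The classifier is gradient-boosted trees (depth 3, 200
rounds, η = 0.1) with 80% row and 30% feature subsampling per boosting
iteration, scored by held-out ROC-AUC under repeated (k = 10, n = 3)
stratified cross-validation, against a null whose labels are permuted once
per repeat; real and null per-fold AUCs are compared by a one-sided
rank-sum test.

One deliberate deviation: rebalancing happens *inside each training fold
only*, never before the split. Resampling before cross-validation leaks
synthetic copies of held-out minority trials into training and inflates AUC
above chance even for pure-noise labels; the in-fold order keeps noise
labels at chance, which the tests assert across 20 seeds. The
resample-before-CV ordering remains available behind
`rebalance_mode = "before_cv"` for comparison with the source procedure.

## What the generators emulate — and what they do not

Each generator is a pure function of its parameters and a seed (bit-identical
reruns) and returns machine-readable ground truth.

- **ECoG**: 1/f-shaped Gaussian background band-limited to 0.1–100 Hz; SWDs
  as fundamental + half-weight second harmonic + a rectified, exponentiated
  "spike" component, with 0.2 s cosine ramps, event RMS defaulting to 5× the
  background RMS (the source does not report SWD amplitude; 5× is the
  exposed stand-in). This reproduces the spectral signature the detector
  keys on; it is not a biophysical thalamocortical seizure model.
- **Sessions**: cue lengths and correct sides in near-equal shuffled counts;
  outcomes from per-cue psychometric probabilities; log-normal reaction
  times with a higher median on incorrect trials; the 30 s post-error
  timeout; optional port perseveration.
- **Photometry**: 20 Hz dual-wavelength traces with difference-of-exponential
  transients on the 470 channel only and a low-passed shared motion artifact
  scaled differently per channel — recoverable by the least-squares step. No
  bleaching, hemodynamics, or rig optics.
- **Laminar**: a sink profile with flanking balanced sources, integrated
  twice across depth so the CSD analysis is its exact inverse; alpha-function
  time course scaled per stimulation intensity (100–500 µA).
- **IPSP trains**: 20 pulses at 40 Hz over 0.5 s, each releasing with
  probability p an exponential hyperpolarizing IPSP.
- **Noisy current**: 150 pA DC plus white noise convolved with a 3 ms alpha
  kernel, low-passed at 100 Hz, fluctuation SD 10 pA.
- **Spiking sweeps**: a leaky integrate-and-fire membrane (τm 20 ms,
  R 200 MΩ, rest −70 mV, threshold −50 mV, reset −60 mV, 2 ms refractory —
  the source fits no cell model; these give ~10–30 spikes per 0.5 s under
  the standard injection). "Light" sweeps add a hyperpolarizing conductance
  whose strength is calibrated by deterministic bisection on calibration
  sweeps so the expected spike-count reduction matches the requested
  fraction.

Passing tests on these generators shows the *analysis* stages are correct
and well-calibrated against known ground truth under realistic statistical
structure; it does not certify performance on real recordings, whose
artifacts (electrode drift, chewing/motion EMG, photobleaching, bursting
nonstationarity) the generators intentionally omit.

## Problem sizes and reproducibility

Validation uses 600 s sessions at 1 kHz for detector sweeps (decimated to
200 Hz for the transform), 40–60-trial behavioral sessions, 50-sweep
failure-rate replicates, and 100–200-trial feature matrices for decoding —
sizes at which every statistical check has adequate power while a full run
of the suite stays interactive. Estimator-bias checks (failure rate) average
several independent replicates so binomial sampling noise is not mistaken
for bias. The pipeline derives all stage seeds from one master seed through
a counter-based scheme, and its manifest records an MD5 hash of every output
file; the determinism test reruns the full pipeline and requires
byte-identical hashes.

## Known limitations

- The detector is tuned for SWD-like events; it does not classify other
  seizure types and has no artifact rejection beyond the spectral rules.
- Component windows for CSD quantification are placeholders until set per
  preparation.
- The decoder's hyperparameters beyond the stated subsampling fractions are
  sensible defaults, not tuned values.
- No vendor acquisition formats are read; conversion to the package's
  container is upstream.
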