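---
title: "Methods: slow-oscillation, spindle and ripple analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-oscillation, spindle and ripple analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleeposc)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, the numerical
choices behind them, what the synthetic benchmark shows, and where the
methods' resolution genuinely ends.

## The slow oscillation and its segmentation

During NREM-like sleep and under urethane anesthesia the cortical LFP
alternates at < 1 Hz between a depolarized Up-state and a hyperpolarized
Down-state. `detect_uds()` segments a channel the standard way: the LFP
is band-passed to the SO band (0.1–0.9 Hz), the instantaneous phase
φ(t) is computed from the Hilbert analytic signal, and the two states
are discriminated by the sign of cos φ(t) — equivalently, by the zero
crossings of the SO-filtered trace wherever the envelope is nonzero.
Two gates then apply: a candidate Up-state must last at least
`min_up_s` (0.3 s) and its mean SO-filtered amplitude must exceed
`min_up_amp_mv` (0.05 mV). Candidates that fail either gate are not
deleted but absorbed into the surrounding Down-state; deleting the
whole cycle would bias Down-state lengths upward. Leading and trailing
partial states are discarded, and when a recording is a concatenation
of segments each inter-boundary stretch is segmented independently, so
no state can straddle a splice.

Two readings of the amplitude gate are possible — absolute voltage or
voltage relative to the recording mean. Since the SO-filtered trace is
zero-mean by construction, the package measures the candidate's mean
SO-filtered value relative to zero, the simplest reading consistent
with a 0.05 mV scale; the threshold is a parameter.

**Polarity.** Which side of cos φ = 0 is "Up" depends on electrode
depth. With `polarity = "auto"` and the broadband trace supplied, the
side with the larger mean gamma-band (30–79.9 Hz) envelope is taken as
Up, because fast activity rides the depolarized state; `"pos"`/`"neg"`
force either choice.

**SO metrics.** A cycle is a Down-state plus the following Up-state.
SO frequency is the number of complete cycles divided by the summed
duration of those cycles (not the raw recording length), so discarded
edges cannot bias it. SO amplitude is the per-cycle peak-to-trough of
the SO-filtered trace (Up maximum minus Down minimum), averaged over
cycles.

### The duration resolution limit

A zero-crossing detector can only recover Up/Down duration asymmetry
that survives the SO band-pass. The asymmetry of a cycle of period T
lives in the harmonics of 1/T; when the cycle rate exceeds ~0.45 Hz the
second harmonic leaves the 0.1–0.9 Hz band entirely, and any
band-limited waveform's crossings become equispaced — the detector then
reports near-equal Up and Down durations regardless of the truth. This
is a property of the method, not of an implementation: a periodic
band-limited signal with no in-band harmonics is a sinusoid, and its
crossings bisect the cycle. At the package's default simulation regime
(Up 1.1 s, Down 1.4 s, cycle 2.5 s ≈ 0.4 Hz, second harmonic 0.8 Hz
in-band) durations are recovered within a few percent and state
boundaries within ~35 ms; at a 1.4 s cycle (0.71 Hz) both duration
means collapse toward the 0.70 s midpoint and only the cycle length and
SO frequency remain trustworthy. Users analyzing fast SO regimes should
interpret reported Up/Down durations with this in mind.

## The normalized cycle and band power

`build_phase_vector()` maps each complete cycle to 0–100: 0 at Down
onset, 50 at the Down→Up transition, 100 at Up end, linear within each
state, 40 bins of width 1.25 per state; samples outside complete
cycles are invalid and excluded from every cycle-aligned average.
Binning uses `floor(value / 1.25)`, so transitions land exactly on bin
edges; a state at least 40 samples long occupies all 40 of its bins.

`morlet_band_power()` computes a continuous wavelet transform with
complex Morlet wavelets on a 0.5 Hz grid across the band (both grid
step and the 6-cycle width are parameters — absolute power magnitudes
depend on them, which is why cross-study power values are comparable
only qualitatively). Power is the squared coefficient magnitude,
integrated across the grid by the trapezoidal rule ("area power").
Wavelets are unit-energy normalized, so white-noise area power is
proportional to bandwidth and doubling an amplitude quadruples power —
both properties are tested. `align_power_to_cycle()` averages the power
over all valid samples per bin, pooling cycles of different lengths;
`summarize_cycle_power()` reports Down power (bins 0–39), Up power
(bins 40–79), peak power and the latency to peak as the center of the
argmax bin (ties break toward the earlier bin, so a flat profile
reports 0.625). Any log-transform for group statistics happens in the
reporting stage, never here.

## Spindle and ripple detection

`detect_envelope_events()` implements the conventional envelope
detector: band-pass → z-score against the whole-recording baseline →
Hilbert envelope → centered moving-average smoothing → threshold.
The presets are:

| parameter | spindles | ripples |
|---|---|---|
| band | 8–15 Hz | 80–130 Hz |
| smoothing kernel | 40 ms | 15 ms |
| upper threshold | mean + 2.5 SD | mean + 2 SD |
| lower threshold | 1.5 × mean | mean + 1 SD |
| peak merge gap | 200 ms | 100 ms |
| duration limits | 0.2–2 s | 20–400 ms |

Choices that required judgment:

- *Baseline normalization* is z-scoring of the band-passed signal, which
  makes the thresholds dimensionless and channels comparable.
- *Upper threshold* is mean + k·SD of the smoothed envelope (the usual
  reading of a "k × SD" rule); k is a parameter.
- *Ripple lower threshold*: a nominal 4 × SD lower bound would exceed
  the 2 × SD upper bound and cannot delimit event edges; the working
  default is mean + 1 SD, with the nominal rule available behind
  `ripple_params(literal_lower = TRUE)` (which warns).
- *Merging precedes duration filtering*: two nearby sub-threshold-length
  bursts can jointly form one valid event.
- *Event amplitude* is the peak of the smoothed, baseline-normalized
  band envelope, not the raw LFP peak — within an event the raw LFP is
  dominated by the SO itself.
- *Instantaneous frequency* is defined as band-passed cycles above the
  upper threshold divided by the time between the two upper-threshold
  crossings. Counting integer cycles quantizes this by 1/duration
  (±3 Hz for a 300 ms event), so the package measures the unwrapped
  analytic-phase advance across that span divided by 2π·span — the
  continuum version of the same quantity, accurate to a fraction of a
  cycle.
- Because both thresholds adapt to the recording (mean and SD of the
  envelope), the operating point depends on event density and
  amplitude: strong, frequent events raise the thresholds and suppress
  noise detections, while on event-free 1/f noise the spindle preset
  admits ~3 spurious detections per minute (pinned as a regression
  bound in the tests) and the permissive ripple preset considerably
  more. On real data this is mitigated by restricting ripple detection
  to histologically confirmed CA1 channels, as the pipeline's
  `ripple_regions` option does.

Event summaries (`compute_event_metrics()`) report amplitude and
duration with population CVs, density per Up-state, the percentage of
high-amplitude events (> 5 × the recording's mean amplitude — a
stringent rule: five identical amplitudes and one 4× outlier yield 0%),
mean instantaneous frequency, and the mean normalized-cycle latency of
event peaks.

## Spike analysis

Spikes are quantized to 1 ms. Units firing under 10 spikes/min are
excluded from firing analysis; coherence additionally requires
30 spikes/min. `state_firing_metrics()` labels spikes within complete
cycles by interval membership; rates divide counts by state occupancy,
percentages are over within-cycle spikes, the total rate is over the
whole recording irrespective of state, and Up-state ISI statistics use
only within-state pairs (cross-Down intervals conflate state structure
with unit properties).

`spike_so_coherence()` bins the train at the LFP rate and estimates the
magnitude-squared coherence C_xy(f) = |P_xy|²/(p_xx·p_yy) by Welch
averaging: 60 s Hann-tapered segments, 50% overlap, per-segment mean
removal (all parameters). Sixty-second segments give ~0.017 Hz
resolution, enough to localize a maximum in the 0.1–0.9 Hz search band;
absolute coherence values are estimator-dependent and comparable only
within a fixed configuration. For null calibration,
`coherence_null_bound()` provides the exact finite-sample quantile
1 − α^(1/(L−1)) of the estimate under independence. That formula is
exact for L *disjoint* segments, so the package evaluates it with the
disjoint-segment count, where it is mildly conservative for the
overlapped estimator; and a pointwise quantile is meaningful at a
frequency chosen a priori (the SO frequency), not for the maximum over
the ~48 bins of the search band, whose null exceedance rate is far
higher.

## The synthetic generator

`simulate_recording()` builds, from one seed, a recording with known
ground truth. Independent substreams drive states, events, spikes and
noise, so changing one component leaves the others bit-identical.

- **States**: alternating Down/Up durations from gamma (default,
  CV 0.3 — urethane SO is regular) or lognormal distributions,
  truncated to tile the recording exactly. Defaults: Up 1.1 s,
  Down 1.4 s (~0.4 Hz SO), chosen as a typical urethane regime whose
  asymmetry is inside the detector's resolution (see above).
- **SO waveform**: each Up-state is a plateau with 150 ms cosine
  shoulders *centered on the planted transitions*, riding on a
  hyperpolarized baseline; the whole component is mean-removed and
  rescaled once so that the mean per-cycle peak-to-trough of its
  SO-band-filtered version equals `so_amplitude_mv` (default 0.8 mV).
  Centering the shoulders puts each edge's mid-height — where a
  band-limited zero crossing localizes — on the transition itself,
  making the planted boundaries well-defined for an unbiased detector;
  the band-pass otherwise absorbs roughly 1 − 4/π of a two-level
  waveform's excursion, which the rescaling compensates.
- **Bursts**: per Up-state band-limited bursts (default gamma band,
  0.06 mV) with a beta-density envelope whose mode sits at
  `peak_latency_pct` (default 65) of the normalized cycle — an
  analytically placed truth for the latency estimator.
- **Events**: Hann-windowed sinusoids at the configured frequencies
  (11 Hz spindles near Up onset, 100 Hz ripples anywhere in the Up-
  state), with analytically known envelope and instantaneous frequency.
  The per-Up count is deterministic (`floor(rate)` plus a Bernoulli
  fractional part), capped by what fits with a safety gap, so planted
  events cannot collide and confound detector scoring.
- **Spikes**: per-unit inhomogeneous Poisson trains, 3 Hz on Up and
  0.3 Hz on Down by default, quantized to 1 ms and labelled.
- **Noise**: 1/f-amplitude Gaussian noise (default 0.03 mV SD,
  flattened below 0.1 Hz) and a 50 Hz line sinusoid (0.02 mV). The
  defaults put planted spindles and ripples at roughly 12× and 21×
  their band's noise SD — squarely in the detectable regime real
  event detection presumes.

What the benchmark does *not* emulate: non-stationarity (drowsiness
drifts, REM-like episodes), waveform diversity (K-complexes,
sharp-wave deflections under ripples), harmonically rich spindles,
movement or electrode artifacts, and volume conduction between
channels. Passing recovery tests on this benchmark therefore
demonstrates correctness of the estimators under the stated model, not
field-grade robustness on arbitrary recordings.

## Numerical choices

- **All filters are zero-phase frequency-domain filters** with purely
  real gains: an IIR realization of a 0.1–0.9 Hz band-pass at a 1 kHz
  rate is numerically fragile (normalized corner ~10⁻⁴), while the
  FFT filter is exact, stable at any band, and phase-perfect — which
  matters because state boundaries and event latencies are
  phase-derived. Inputs are padded by odd (anti-symmetric) reflection,
  the conventional forward–backward-filtering extension, so transients
  cannot wrap; band transitions are raised-cosine, one-tenth of the
  edge frequency (clamped to 0.05–4 Hz), reaching full stop within one
  octave.
- **The SO filter used for state detection** (`so_filter()`) widens the
  upper transition to 0.9–1.2 Hz. A sharp cutoff just above the band
  discards the waveform shape that localizes state edges; the gentle
  shoulder roughly halves boundary error while still meeting the
  attenuation contract. Band-power quantification keeps the sharp
  default, where leakage control matters instead.
- The line notch is a full stop within ±1 Hz with cosine shoulders to
  ±2 Hz — ≥30 dB at the line, unit gain beyond 2 Hz.
- Welch coherence is clamped to [0, 1] (the estimator is bounded by
  Cauchy–Schwarz; floating point can spill by an ulp), and fewer than
  4 averaging segments is an error rather than an unstable estimate.
- Degenerate inputs fail loudly: constant series cannot be z-scored,
  zero-variance envelopes cannot be thresholded, an empty normalized-
  cycle bin names itself, and an empty event list summarizes as absent
  values, not zeros.
- Recovery tests run on 30–600 s of synthetic signal at 1 kHz — 600 s
  (~240 cycles, ~4500 spikes) where distributional recovery is
  asserted, shorter where the check is structural; these sizes give the
  quoted tolerances comfortable margins while keeping the whole suite
  in a few minutes.

## Persistence

Recordings are stored as a plain-text directory — `lfp.csv` with
17-significant-digit samples (bit-exact round trip), `channels.csv`,
and `meta.json` with the sampling rate and concatenation boundaries;
events and spikes are CSV. `run_pipeline()` writes tidy per-channel
tables plus a manifest with the package version and a hash of the
analysis-relevant configuration; identical inputs reproduce every
output byte for byte.
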