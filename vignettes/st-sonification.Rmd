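---
title: "Grouped lead scans: design and methods of the ST sonification engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouped lead scans: design and methods of the ST sonification engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsonify)
```

## The monitoring problem

STEMI diagnosis rests on ST-segment deviation across the 12 ECG leads:
elevation in contiguous leads localises the occluded vessel (V1–V4 for
the anterior wall; II, III, aVF with reciprocal depression in I/aVL for
the inferior wall). `ecgsonify` renders this 12-dimensional, slowly
evolving quantity as sound, so that a caregiver attending to the
patient can track it by ear. This vignette documents the model, every
tunable parameter, the synthetic data the tests rely on, and the design
choices made where the method left details open.

## From waveform to five levels

For each beat the R time anchors two windows per lead:

* **Baseline**: mean signal over the PR segment, `[R − 120, R − 40] ms`
  (`baseline_window_ms`). The PR segment is the conventional
  isoelectric reference and is the part of the cycle least affected by
  repolarisation changes.
* **ST window**: mean over 20 ms (`st_window_ms`) centred at
  J + 60 ms, with the J point approximated as R + 80 ms
  (`j_offset_ms`, `st_delay_ms`). J+60 is a standard clinical
  measurement point; the offsets are configurable because J varies
  with QRS width and heart rate.

`st` is the difference of the two means, in mV, which makes the
measure exactly invariant to constant baseline shifts and linear in any
injected ST offset — both asserted as properties in the test suite.
Beat detection (band-passed lead II, squared derivative, moving-window
integration, 250 ms refractory period) is deliberately simple: the
engine targets clean monitor-grade or synthetic signals, and
pre-annotated beat times bypass it entirely. Arrhythmia, pacing
artifacts and noisy field recordings are out of scope.

The classifier applies the five-band cutoff rule (±0.1, ±0.2 mV,
`cutoffs_mv`) with the boundary conventions taken literally from the
printed inequalities: ±0.1 and 0.2 belong to the *moderate* bands, −0.2
to s2, and e2 is strictly open at 0.2. The tests pin every boundary and
verify that the five half-open intervals partition the real line with
level ordinal non-decreasing in `st`.

## From levels to sound

One scan = six tones at `inter_tone_ms` = 120 ms spacing. L1 covers the
limb leads in Cabrera order (with inverted aVR as −aVR so the sequence
sweeps the frontal plane monotonically), L2 the precordials V1–V6, so
the tone *position within the scan* encodes the lead. L1 fires on the
first detected beat and every `scan_period_beats` = 8 beats thereafter
(immediate feedback at monitoring start, rather than waiting out the
first period); L2 follows `l2_offset_beats` = 2 beats later. Scans
whose offset beat falls beyond the record end are dropped, not
extrapolated. The measurements feeding a scan come from the trigger
beat itself (`st_average_beats` = 1) for maximal responsiveness to
transients; a longer averaging window is available for noisy input.

Tone parameters per level are a pure table lookup
(`toneMap()`): semitones (−8, −5, 0, 4, 7), durations (100, 80, 50,
80, 100) ms, harmonics (3, 3, 1, 3, 3), levels (15, 5, 0, 5, 15) dB,
and pitch f(k) = f₀·2^(k/12) with f₀ = 554 Hz — the QRS beep pitch, so
deviation is heard as an interval against an ever-present anchor.

### Synthesis choices

The synthesiser is additive: `n` partials at f, 2f, …, nf with 1/h
amplitude roll-off, a 5 ms linear attack (declick), and a fade-out
envelope `(1 − t/d)^γ` with curvature
`γ(|st|) = max(0.5, 3 − 5·min(|st|, 0.4))` — monotonically
non-increasing in |st|, so extreme deviations sustain while isoelectric
tones decay quickly. The exact curvature law and the QRS beep shape
(60 ms sine at f₀ with a 15 ms exponential decay) are this package's
conventions; only the monotone requirement is inherent to the design.

Two normalisations are deliberate design decisions: the harmonic stack
and the complete amplitude envelope are each scaled to unit energy, so
the mapped dB level is the *sole* determinant of a tone's RMS.
Without this, brightness (3 partials vs 1) and curvature (shallow vs
steep fade) would each shift loudness by 1–3 dB and blur the level
dimension of the mapping; with it, the e2/IE RMS ratio equals
10^(15/20) identically, which the tests assert. Rendering mixes every
QRS beep and tone additively at `round(onset × sample_rate)` (sample-
exact; the timing property holds to < 1 ms by construction) and applies
one global peak-normalisation to −1 dBFS — absolute playback level is
irrelevant offline, relative levels are preserved, clipping is
impossible. Output is mono 16-bit PCM WAV at 44.1 kHz.

## The synthetic scenario generator

`generateScenario()` emulates the standardized simulation scenario the
design was evaluated in: a metronomic beat train (default 80 bpm), an
isoelectric first phase, and at `transition_time` (default 90 s) an
instantaneous switch to the infarct pattern — matching how a patient
simulator flips ECG programs; an optional linear ramp and RR jitter
exist for robustness experiments. Beats are sums of five Gaussian bumps
(P, Q, R, S, T) with a small per-lead amplitude table giving plausible
axes and R-wave progression. The ST offset is injected as a smooth
flat-topped window from ~J to the end of the T wave, which leaves both
the PR baseline window and the next beat's windows untouched — so the
injected offset *is* the ground-truth `st`, recoverable by the
measurement stage to < 0.02 mV on noiseless input (a parameter-recovery
property the suite checks across all pattern × severity classes).

Severity magnitudes are generator conventions chosen so the classes
land in the intended bands: weak 0.12 mV (e1), moderate 0.25 mV (e2),
severe 0.40 mV (e2) on affected leads. Reciprocal depression in
inferior STEMI is −0.6 × the elevation: −0.5 would put the severe case
exactly on the −0.2 mV cutoff, where the true class is ill-posed under
any measurement perturbation, so the factor was set to keep every
injected value strictly inside a band (severe −0.24 mV → s2, moderate
−0.15 → s1, weak −0.072 → IE). A transition time beyond the record end
is allowed and simply means the pattern never appears.

What the generator does *not* emulate: baseline wander, EMG and mains
noise (only additive white Gaussian noise is provided), ectopy or
atrial fibrillation, morphology pathology beyond the ST shift, and
electrode artifacts. Passing tests therefore demonstrate correctness of
the measurement-classification-mapping-synthesis chain, not clinical
robustness of the beat detector or ST estimator on field recordings.

## Numerical and interface choices

* Amplitudes are mV everywhere internally; readers convert (the
  waveform-record reader honours per-signal gain, written records use
  1000 adu/mV, i.e. 0.001 mV quantization).
* Beat indices are 0-based; times are seconds from record start.
* ECG tables are CSV with a `time_s` column (rate inferred, uniformity
  enforced) or a YAML sidecar carrying `sampling_rate`.
* Configuration files are YAML with exactly the `sonifyConfig()`
  argument names; unknown keys are rejected.
* Synthesis errors out when `n·f` reaches Nyquist rather than silently
  aliasing.
* Problem sizes in the shipped tests are chosen for fast, deterministic
  runs: 10–60 s noiseless scenarios for recovery checks, one 160 s
  (≈210-beat) noisy scenario for the 95 %-agreement check, 1000 random
  scan vectors against the brute-force mapping oracle, and 2^17-point
  zero-padded FFTs (0.34 Hz resolution) for all spectral assertions.

## Known limitations

The QRS detector is not clinical grade and is untested on real-world
noise; ST measurement assumes a reasonably normal QRS width (fixed
J-point offset); the lead-amplitude table is a single stylised
morphology, not a population; and the renderer is offline — real-time
streaming with bounded latency would need a different architecture.
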