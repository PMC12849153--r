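# ecgsonify

Auditory display of ST-segment deviation in the 12-lead ECG.

During prehospital care of suspected acute coronary syndrome, the
diagnostic quantity on the monitor is the ST-segment deviation of each
of the 12 ECG leads — elevation above ~0.1–0.2 mV localised to
contiguous leads signals STEMI and the need for immediate
revascularisation. A clinician busy with the patient cannot watch 12
traces continuously. `ecgsonify` implements an event-based
parameter-mapping sonification that turns the 12 per-lead ST values
into structured tone sequences riding on the familiar QRS beep, so a
developing ST elevation is *heard* without looking at the screen. It is
aimed at auditory-display researchers and simulation educators; it is an
offline research engine, not a medical device.

## The method

For every beat and lead, the ST deviation `st` (mV) is measured at the
conventional J+60 ms point against the PR-segment baseline and assigned
to one of five levels:

| level | meaning | rule |
|---|---|---|
| s2 | strongly suppressed | st ≤ −0.2 mV |
| s1 | moderately suppressed | −0.2 < st ≤ −0.1 mV |
| IE | close to isoelectric | \|st\| < 0.1 mV |
| e1 | moderately elevated | 0.1 ≤ st ≤ 0.2 mV |
| e2 | strongly elevated | st > 0.2 mV |

Each level maps to a short tone relative to the QRS reference pitch
p₀ (f₀ = 554 Hz), with frequency f(k) = f₀·2^(k/12):

* semitone offsets k = (−8, −5, 0, 4, 7)
* durations d = (100, 80, 50, 80, 100) ms
* harmonic partials n = (3, 3, 1, 3, 3)
* levels l = (15, 5, 0, 5, 15) dB

for (s2, s1, IE, e1, e2) respectively, and |st| flattens the tone's
fade-out so extreme deviations sustain longer. The leads are played as
two *grouped lead scans* of six tones each (120 ms apart): L1 walks the
limb leads in Cabrera order {aVL, I, −aVR, II, aVF, III} on every 8th
beat, and L2 walks the precordial leads {V1…V6} two beats later. Twelve
isoelectric leads sound as two even runs at the reference pitch; an
anterior STEMI turns the first four L2 tones into loud, bright,
long tones a fifth (+7 semitones) above it.

A synthetic 12-lead generator (Gaussian-bump P-QRS-T templates, graded
anterior/inferior STEMI patterns, configurable heart rate, transition
time and noise) makes the whole chain reproducible without patient
data.

## Worked example

Simulate the default monitoring scenario — 80 bpm, isoelectric start,
severe anterior STEMI appearing at 90 s — and sonify it:

```r
library(ecgsonify)
paths <- runSimulate("demo", pattern = "anterior_stemi", severity = "severe",
                     total_duration = 120, transition_time = 90, seed = 1)
log <- read.delim(paths[["events"]])
subset(log, time_s >= 90 & set == "L2" & time_s == min(time_s[time_s >= 90 & set == "L2"]))
```

This writes `demo_ecg.csv`, `demo_truth.tsv`, `demo.wav` and the event
log `demo_events.tsv`, and the first precordial scan after the
transition reads:

```
 time_s set lead        st_mv level semitone  freq_hz
  91.95  L2   V1 3.999190e-01    e2        7 830.0621
  91.95  L2   V2 4.001192e-01    e2        7 830.0621
  91.95  L2   V3 4.001334e-01    e2        7 830.0621
  91.95  L2   V4 4.000997e-01    e2        7 830.0621
  91.95  L2   V5 6.654087e-05    IE        0 554.0000
  91.95  L2   V6 5.568713e-05    IE        0 554.0000
```

The injected 0.40 mV elevation on V1–V4 is recovered to within a
fraction of a millivolt, classified *strongly elevated* (e2) and pitched
at 554·2^(7/12) ≈ 830 Hz, while the unaffected V5–V6 stay at the
reference pitch; every scan before 90 s is entirely isoelectric. Listen
to `demo.wav` to hear the change. A thin command-line wrapper with the
same behaviour lives at `inst/cli/ecgsonify.R`
(`Rscript inst/cli/ecgsonify.R simulate --pattern anterior_stemi --seed 1 --output demo`).

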