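# reference linear amplitude of a 0 dB (IE) tone; leaves headroom for the
# +15 dB extreme-level tones and the energy-normalised envelope peak
.toneRefAmp <- 0.04

#' Equal-temperament pitch offset
#'
#' Frequency of a tone offset by \code{k} semitones from a reference:
#' f(k) = f0 * 2^(k/12).
#'
#' @param f0 reference frequency, Hz (> 0).
#' @param k semitone offset (may be fractional or a vector).
#' @return frequency in Hz.
#' @export
#' @examples
#' toneFreq(554, 0)    # 554
#' toneFreq(554, 12)   # one octave: 1108
#' toneFreq(554, 7)    # ~830.06
toneFreq <- function(f0, k) {
  if (!is.numeric(f0) || any(f0 <= 0)) stop("f0 must be positive")
  f0 * 2^(k / 12)
}

#' Decibels to linear amplitude gain
#'
#' @param l level in dB (amplitude convention): gain = 10^(l/20).
#' @return linear amplitude factor.
#' @export
#' @examples
#' dbToGain(0)    # 1
#' dbToGain(20)   # 10
dbToGain <- function(l) {
  if (any(!is.finite(l))) stop("level must be finite")
  10^(l / 20)
}

#' Fade-out curvature as a function of |st|
#'
#' Exponent gamma of the fade-out envelope (1 - t/d)^gamma. Gamma is
#' non-increasing in |st|: tones for extreme ST deviations fade out less
#' steeply (smaller gamma, more sustained), making them more salient.
#' Default law: gamma = max(0.5, 3 - 5 * min(|st|, 0.4)).
#'
#' @param st ST deviation, mV (sign ignored); vectorized.
#' @param cfg a [sonifyConfig()] carrying the curvature parameters.
#' @return curvature exponent(s) gamma > 0.
#' @export
fadeCurvature <- function(st, cfg = sonifyConfig()) {
  pmax(cfg$curvature_min,
       cfg$curvature_max - cfg$curvature_slope *
         pmin(abs(st), cfg$curvature_st_cap))
}

# complete amplitude envelope (attack ramp x power-law fade), energy-
# normalised to unit RMS so the dB level alone sets tone energy
toneEnvelope <- function(nSamp, sampleRate, gamma, attackMs) {
  t <- (seq_len(nSamp) - 1) / sampleRate
  d <- nSamp / sampleRate
  env <- (1 - t / d)^gamma
  if (attackMs > 0) env <- env * pmin(t / (attackMs / 1000), 1)
  rms <- sqrt(mean(env^2))
  if (rms > 0) env <- env / rms
  env
}

#' Synthesize one scan tone
#'
#' Additive synthesis of a short pitched tone: \code{harmonics} partials
#' at f, 2f, ..., nf with 1/h amplitude roll-off (the stack is
#' energy-normalised so brightness does not change loudness), scaled by
#' \code{dbToGain(level_db)}, and shaped by a short attack ramp plus the
#' fade-out envelope (1 - t/d)^gamma with gamma = [fadeCurvature()](|st|).
#' The envelope is likewise energy-normalised, so the RMS of the rendered
#' tone is exactly proportional to its linear gain.
#'
#' @param freq_hz fundamental frequency, Hz.
#' @param duration_ms tone duration, ms.
#' @param harmonics number of harmonic partials (>= 1).
#' @param level_db level relative to the isoelectric reference tone, dB.
#' @param st ST deviation driving the fade-out curvature, mV (default 0).
#' @param cfg a [sonifyConfig()] (sample rate, attack, curvature law).
#' @return an [AudioBuffer-class] of length
#'   \code{round(duration_ms/1000 * sample_rate)} samples.
#' @export
#' @examples
#' ie <- synthTone(554, 50, 1, 0)
#' duration(ie)  # 0.05 s
synthTone <- function(freq_hz, duration_ms, harmonics, level_db, st = 0,
                      cfg = sonifyConfig()) {
  stopifnot(inherits(cfg, "SonifyConfig"), freq_hz > 0, duration_ms > 0,
            harmonics >= 1)
  sr <- cfg$sample_rate
  if (harmonics * freq_hz >= sr / 2) {
    stop(sprintf("harmonic %d of %.0f Hz reaches the Nyquist frequency; use a sample rate above %.0f Hz",
                 harmonics, freq_hz, 2 * harmonics * freq_hz))
  }
  nSamp <- round(duration_ms / 1000 * sr)
  t <- (seq_len(nSamp) - 1) / sr
  amps <- 1 / seq_len(harmonics)
  amps <- amps / sqrt(sum(amps^2))       # unit-energy harmonic stack
  wave <- numeric(nSamp)
  for (h in seq_len(harmonics)) {
    wave <- wave + amps[h] * sin(2 * pi * h * freq_hz * t)
  }
  env <- toneEnvelope(nSamp, sr, fadeCurvature(st, cfg), cfg$attack_ms)
  AudioBuffer(.toneRefAmp * dbToGain(level_db) * wave * env, sr)
}

#' Synthesize the QRS reference beep
#'
#' The familiar pulse-oximeter-style beat tone: a sine at the reference
#' pitch f0 with a fast exponential decay (time constant 15 ms), fixed
#' duration \code{qrs_tone_ms} (default 60 ms), energy-matched to an
#' isoelectric scan tone via \code{qrs_level_db}.
#'
#' @param cfg a [sonifyConfig()].
#' @return an [AudioBuffer-class].
#' @export
synthQrsTone <- function(cfg = sonifyConfig()) {
  stopifnot(inherits(cfg, "SonifyConfig"))
  sr <- cfg$sample_rate
  nSamp <- round(cfg$qrs_tone_ms / 1000 * sr)
  t <- (seq_len(nSamp) - 1) / sr
  env <- exp(-t / 0.015)
  if (cfg$attack_ms > 0) env <- env * pmin(t / (cfg$attack_ms / 1000), 1)
  env <- env / sqrt(mean(env^2))
  AudioBuffer(.toneRefAmp * dbToGain(cfg$qrs_level_db) *
                sin(2 * pi * cfg$f0 * t) * env, sr)
}
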