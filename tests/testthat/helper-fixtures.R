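# Shared fixtures and small analysis oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A recording that is exactly zero everywhere except a narrow triangular
# R spike at each given time: ST and PR windows see identically zero
# signal, so measured st is exactly 0.
spikeRecording <- function(rTimes, fs = 500, dur = max(rTimes) + 1,
                           amp = 1, halfWidthS = 0.01) {
  n <- round(dur * fs)
  x <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  for (rt in rTimes) {
    idx <- which(abs(t - rt) <= halfWidthS)
    x[idx] <- x[idx] + amp * (1 - abs(t[idx] - rt) / halfWidthS)
  }
  sig <- matrix(rep(x, 12), ncol = 12,
                dimnames = list(NULL, ecgLeads()))
  EcgRecording(sig, samplingRate = fs)
}

# Magnitude spectrum of an AudioBuffer, zero-padded for fine resolution.
magSpectrum <- function(buf, nfft = 2^17) {
  x <- audioSamples(buf)
  stopifnot(length(x) <= nfft)
  X <- abs(stats::fft(c(x, numeric(nfft - length(x)))))
  half <- seq_len(nfft %/% 2)
  list(freq = (half - 1) * samplingRate(buf) / nfft, mag = X[half])
}

# Frequency of the strongest spectral bin.
peakFreq <- function(buf) {
  sp <- magSpectrum(buf)
  sp$freq[which.max(sp$mag)]
}

# Number of spectral partials: prominent local maxima more than
# `dbAbove` dB above the median bin (noise floor), at least `minSepHz`
# apart, and within `relFloorDb` of the strongest peak (rejecting
# leakage sidelobes).
countPartials <- function(buf, dbAbove = 40, minSepHz = 250,
                          relFloorDb = 25) {
  sp <- magSpectrum(buf)
  m <- sp$mag
  n <- length(m)
  thr <- stats::median(m) * 10^(dbAbove / 20)
  isMax <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n],
             FALSE)
  cand <- which(isMax & m > thr & m > max(m) * 10^(-relFloorDb / 20))
  cand <- cand[order(m[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in cand) {
    f <- sp$freq[i]
    if (!length(kept) || all(abs(kept - f) >= minSepHz)) kept <- c(kept, f)
  }
  length(kept)
}

# Peak-normalized amplitude envelope via a rolling maximum of |x|.
toneEnvArea <- function(buf, winS = 0.002) {
  x <- abs(audioSamples(buf))
  w <- max(1L, round(winS * samplingRate(buf)))
  env <- vapply(seq_along(x), function(i) {
    max(x[max(1L, i - w):min(length(x), i + w)])
  }, numeric(1))
  env <- env / max(env)
  sum(env) / samplingRate(buf)
}

# Cross-correlation refinement of a tone onset: best lag (s) of
# `template` inside `buf` within +/- searchS around `about`.
xcorrOnset <- function(buf, template, about, searchS = 0.005) {
  x <- audioSamples(buf)
  tp <- audioSamples(template)
  sr <- samplingRate(buf)
  center <- round(about * sr) + 1L
  lags <- (center - round(searchS * sr)):(center + round(searchS * sr))
  score <- vapply(lags, function(i0) {
    i1 <- i0 + length(tp) - 1L
    if (i0 < 1L || i1 > length(x)) return(-Inf)
    sum(x[i0:i1] * tp)
  }, numeric(1))
  (lags[which.max(score)] - 1L) / sr
}

# Independent brute-force oracle for one scan: literal inequalities and
# the literal published parameter table, no package lookup functions.
oracleScan <- function(set, triggerTime, st, f0 = 554) {
  tab <- list(
    s2 = list(k = -8, d = 100, n = 3, l = 15),
    s1 = list(k = -5, d = 80, n = 3, l = 5),
    IE = list(k = 0, d = 50, n = 1, l = 0),
    e1 = list(k = 4, d = 80, n = 3, l = 5),
    e2 = list(k = 7, d = 100, n = 3, l = 15)
  )
  lev <- vapply(st, function(s) {
    if (s <= -0.2) "s2"
    else if (s > -0.2 && s <= -0.1) "s1"
    else if (abs(s) < 0.1) "IE"
    else if (s >= 0.1 && s <= 0.2) "e1"
    else "e2"
  }, character(1))
  leads <- if (set == "L1") c("aVL", "I", "negAVR", "II", "aVF", "III") else
    paste0("V", 1:6)
  data.frame(
    set = set, slot = 1:6, lead = leads,
    onset = triggerTime + (0:5) * 0.120, st = st, level = lev,
    semitone = vapply(lev, function(v) tab[[v]]$k, numeric(1)),
    freq_hz = f0 * 2^(vapply(lev, function(v) tab[[v]]$k, numeric(1)) / 12),
    duration_ms = vapply(lev, function(v) tab[[v]]$d, numeric(1)),
    harmonics = vapply(lev, function(v) tab[[v]]$n, numeric(1)),
    level_db = vapply(lev, function(v) tab[[v]]$l, numeric(1)),
    row.names = NULL
  )
}
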