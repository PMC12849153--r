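#' Render scan events and QRS tones into an audio timeline
#'
#' Offline mix of the full auditory scene: every beat contributes a QRS
#' beep at its R time, every scan tone is placed at its scheduled onset,
#' overlapping sounds sum, and the final buffer is peak-normalized to
#' -1 dBFS with a single global gain (so relative levels are preserved
#' and clipping is impossible).
#'
#' @param tones tone-spec table from [buildScanEvents()] (may be empty).
#' @param beats beat table (columns \code{index}, \code{r_time}); each
#'   beat gets a QRS tone. May be empty.
#' @param cfg a [sonifyConfig()].
#' @param totalDuration output length in seconds; default: just long
#'   enough for the last scheduled sound.
#' @return an [AudioBuffer-class], mono, at \code{cfg$sample_rate}.
#' @export
renderAudio <- function(tones, beats, cfg = sonifyConfig(),
                        totalDuration = NULL) {
  stopifnot(inherits(cfg, "SonifyConfig"))
  sr <- cfg$sample_rate
  lastEnd <- 0
  if (!is.null(beats) && nrow(beats)) {
    lastEnd <- max(lastEnd, max(beats$r_time) + cfg$qrs_tone_ms / 1000)
  }
  if (!is.null(tones) && nrow(tones)) {
    lastEnd <- max(lastEnd, max(tones$onset + tones$duration_ms / 1000))
  }
  if (is.null(totalDuration)) totalDuration <- lastEnd
  totalDuration <- max(totalDuration, lastEnd)
  n <- max(1L, ceiling(totalDuration * sr))
  mix <- numeric(n)

  addAt <- function(mix, buf, onset) {
    i0 <- round(onset * sr) + 1L
    i1 <- i0 + nSamples(buf) - 1L
    if (i1 > length(mix)) {    # defensive: truncate at buffer end
      keep <- length(mix) - i0 + 1L
      if (keep <= 0L) return(mix)
      mix[i0:length(mix)] <- mix[i0:length(mix)] + audioSamples(buf)[seq_len(keep)]
      return(mix)
    }
    mix[i0:i1] <- mix[i0:i1] + audioSamples(buf)
    mix
  }

  if (!is.null(beats) && nrow(beats)) {
    qrs <- synthQrsTone(cfg)
    for (rt in beats$r_time) mix <- addAt(mix, qrs, rt)
  }
  if (!is.null(tones) && nrow(tones)) {
    for (i in seq_len(nrow(tones))) {
      tb <- synthTone(tones$freq_hz[i], tones$duration_ms[i],
                      tones$harmonics[i], tones$level_db[i],
                      st = tones$st[i], cfg = cfg)
      mix <- addAt(mix, tb, tones$onset[i])
    }
  }
  peak <- max(abs(mix))
  target <- 10^(-1 / 20)               # -1 dBFS
  if (peak > 0) mix <- mix * (target / peak)
  AudioBuffer(mix, sr)
}

#' Write / read 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE codec: mono, 16-bit signed little-endian PCM at the
#' buffer's sample rate. Round-tripping a buffer reproduces it within one
#' quantization step (2^-15).
#'
#' @param buf an [AudioBuffer-class].
#' @param path output (input) file path.
#' @return \code{writeWav}: \code{path} invisibly; \code{readWav}: an
#'   [AudioBuffer-class].
#' @export
writeWav <- function(buf, path) {
  stopifnot(is(buf, "AudioBuffer"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write WAV: ", path))
  on.exit(close(con))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(audioSamples(buf) * 32767))))
  sr <- as.integer(round(samplingRate(buf)))
  dataBytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(1L, con, size = 2L, endian = "little")           # mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little")      # byte rate
  writeBin(2L, con, size = 2L, endian = "little")           # block align
  writeBin(16L, con, size = 2L, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname writeWav
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4L, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file: ", path)
  sr <- NULL; bits <- NULL; nch <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size = 2L, n = 2L, endian = "little")
      nch <- fmt[2]
      sr <- readBin(con, "integer", size = 4L, endian = "little")
      readBin(con, "integer", size = 4L, endian = "little")
      readBin(con, "integer", size = 2L, endian = "little")
      bits <- readBin(con, "integer", size = 2L, endian = "little")
      if (sz > 16L) readBin(con, "raw", n = sz - 16L)
    } else if (id == "data") {
      if (is.null(bits) || bits != 16L || nch != 1L) {
        stop("only mono 16-bit PCM WAV is supported")
      }
      samples <- readBin(con, "integer", size = 2L, signed = TRUE,
                         n = sz %/% 2L, endian = "little")
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  AudioBuffer(pmax(-1, pmin(1, samples / 32767)), sr)
}
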