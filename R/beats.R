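#' Detect QRS beats in an ECG recording
#'
#' A simple energy-based detector adequate for clean monitoring signals:
#' lead II is band-passed (5-30 Hz Butterworth, zero phase), differenced
#' and squared, then integrated over a 120 ms moving window; peaks above
#' an adaptive threshold separated by a 250 ms refractory period mark
#' beats, and each R time is refined to the largest absolute band-passed
#' deflection within +/-80 ms. When beat annotations are already
#' available, pass them via \code{annotations} to bypass detection.
#'
#' @param rec an [EcgRecording-class] of at least 2 s duration.
#' @param lead lead used for detection (default \code{"II"}).
#' @param refractory_s minimum spacing between beats, seconds.
#' @param threshold_frac detection threshold as a fraction of the 99th
#'   percentile of the integrated energy signal.
#' @param annotations optional numeric vector of known R times (s); when
#'   supplied, it is validated and returned as-is.
#' @return data.frame with columns \code{index} (0-based beat number) and
#'   \code{r_time} (seconds from record start), strictly increasing.
#'   Empty (with a warning) when no beats are found.
#' @export
detectBeats <- function(rec, lead = "II", refractory_s = 0.25,
                        threshold_frac = 0.2, annotations = NULL) {
  stopifnot(is(rec, "EcgRecording"))
  if (!is.null(annotations)) {
    annotations <- as.numeric(annotations)
    stopifnot(all(diff(annotations) > 0),
              all(annotations >= 0), all(annotations <= duration(rec)))
    return(data.frame(index = seq_along(annotations) - 1L,
                      r_time = annotations))
  }
  if (duration(rec) < 2) stop("recording shorter than 2 s")
  fs <- samplingRate(rec)
  x <- leadSignal(rec, lead)
  bf <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  energy <- c(0, diff(xb))^2
  w <- max(1L, round(0.12 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- threshold_frac * stats::quantile(integ, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    warning("no QRS energy found; returning empty beat list")
    return(data.frame(index = integer(0), r_time = numeric(0)))
  }
  above <- integ > thr
  refr <- round(refractory_s * fs)
  half <- round(0.08 * fs)
  n <- length(x)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      lo <- max(1L, i - half); hi <- min(n, j + half)
      r <- lo - 1L + which.max(abs(xb[lo:hi]))
      if (!length(peaks) || r - peaks[length(peaks)] >= refr) {
        peaks <- c(peaks, r)
      }
      i <- max(j + 1L, r + refr)
    } else i <- i + 1L
  }
  if (!length(peaks)) {
    warning("no QRS energy found; returning empty beat list")
    return(data.frame(index = integer(0), r_time = numeric(0)))
  }
  data.frame(index = seq_along(peaks) - 1L, r_time = (peaks - 1L) / fs)
}
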