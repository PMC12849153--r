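#' Measure ST-segment deviation per beat and lead
#'
#' For each (beat, lead) pair, the ST deviation \code{st} (mV) is the
#' mean signal in a short ST window minus the mean signal in the PR
#' baseline window. Window placement follows clinical convention and is
#' configurable through [sonifyConfig()]: the J-point is approximated as
#' R + \code{j_offset_ms} (default 80 ms); the ST window is centred at
#' J + \code{st_delay_ms} (default 60 ms, i.e. the J+60 measurement
#' point) with width \code{st_window_ms} (default 20 ms); the baseline
#' window spans \code{baseline_window_ms} relative to R (default
#' [R-120, R-40] ms, the PR segment). Being a difference of means, the
#' measure is exactly invariant to constant baseline shifts.
#'
#' @param rec an [EcgRecording-class].
#' @param beats beat table from [detectBeats()] (columns \code{index},
#'   \code{r_time}), or a numeric vector of R times.
#' @param leads leads to measure; any of [ecgLeads()] plus
#'   \code{"negAVR"}. Default: the 12 acquired leads plus negAVR.
#' @param cfg a [sonifyConfig()] carrying the measurement windows.
#' @return data.frame with columns \code{beat} (0-based index),
#'   \code{r_time}, \code{lead}, \code{st} (mV), one row per
#'   (beat, lead). Beats whose windows fall outside the record raise an
#'   error.
#' @export
#' @examples
#' out <- generateScenario(scenarioSpec("anterior_stemi", "severe",
#'   total_duration = 20, transition_time = 0))
#' st <- measureSt(out$recording, out$truth$beats, leads = "V2")
#' round(mean(st$st), 2)  # ~0.40 mV injected elevation
measureSt <- function(rec, beats, leads = c(ecgLeads(), "negAVR"),
                      cfg = sonifyConfig()) {
  stopifnot(is(rec, "EcgRecording"), inherits(cfg, "SonifyConfig"))
  if (is.numeric(beats)) {
    beats <- data.frame(index = seq_along(beats) - 1L, r_time = beats)
  }
  stopifnot(is.data.frame(beats), all(c("index", "r_time") %in% names(beats)))
  leads <- normalizeLeadName(leads)
  fs <- samplingRate(rec)
  n <- nSamples(rec)
  stLo <- (cfg$j_offset_ms + cfg$st_delay_ms - cfg$st_window_ms / 2) / 1000
  stHi <- (cfg$j_offset_ms + cfg$st_delay_ms + cfg$st_window_ms / 2) / 1000
  blLo <- cfg$baseline_window_ms[1] / 1000
  blHi <- cfg$baseline_window_ms[2] / 1000

  winIdx <- function(rt, lo, hi) {
    i0 <- round((rt + lo) * fs) + 1L
    i1 <- round((rt + hi) * fs) + 1L
    if (i0 < 1L || i1 > n) {
      stop(sprintf("measurement window [%.3f, %.3f] s outside record (beat at %.3f s)",
                   rt + lo, rt + hi, rt))
    }
    i0:i1
  }

  sig <- vapply(leads, function(ld) leadSignal(rec, ld), numeric(n))
  rows <- vector("list", nrow(beats))
  for (b in seq_len(nrow(beats))) {
    rt <- beats$r_time[b]
    iSt <- winIdx(rt, stLo, stHi)
    iBl <- winIdx(rt, blLo, blHi)
    st <- colMeans(sig[iSt, , drop = FALSE]) -
          colMeans(sig[iBl, , drop = FALSE])
    rows[[b]] <- data.frame(beat = beats$index[b], r_time = rt,
                            lead = leads, st = as.numeric(st))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
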