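#' Schedule grouped lead scans over a beat train
#'
#' The L1 (limb-lead) scan is triggered on the first beat and then every
#' \code{scan_period_beats} beats (default 8); each L2 (precordial) scan
#' fires \code{l2_offset_beats} beats (default 2) after its L1 scan so
#' the two six-tone messages remain easily discernible. L2 scans whose
#' trigger beat lies beyond the end of the record are dropped.
#'
#' @param beats beat table (columns \code{index}, \code{r_time}) with
#'   strictly increasing times.
#' @param cfg a [sonifyConfig()].
#' @return data.frame with columns \code{set} ("L1"/"L2"),
#'   \code{trigger_index} (beat index) and \code{trigger_time} (s),
#'   ordered by time.
#' @export
#' @examples
#' beats <- data.frame(index = 0:19, r_time = (0:19) * 0.75)
#' scheduleScans(beats)  # L1 at beats 0, 8, 16; L2 at 2, 10, 18
scheduleScans <- function(beats, cfg = sonifyConfig()) {
  stopifnot(inherits(cfg, "SonifyConfig"), is.data.frame(beats))
  empty <- data.frame(set = character(0), trigger_index = integer(0),
                      trigger_time = numeric(0))
  if (!nrow(beats)) return(empty)
  stopifnot(all(diff(beats$r_time) > 0))
  nb <- nrow(beats)
  l1pos <- seq(1L, nb, by = cfg$scan_period_beats)   # row positions
  l2pos <- l1pos + cfg$l2_offset_beats
  l2pos <- l2pos[l2pos <= nb]
  sched <- rbind(
    data.frame(set = rep("L1", length(l1pos)),
               trigger_index = beats$index[l1pos],
               trigger_time = beats$r_time[l1pos]),
    data.frame(set = rep("L2", length(l2pos)),
               trigger_index = beats$index[l2pos],
               trigger_time = beats$r_time[l2pos])
  )
  sched[order(sched$trigger_time), , drop = FALSE] -> sched
  rownames(sched) <- NULL
  sched
}

#' Build one six-tone scan event
#'
#' Turns six per-lead ST measurements into six fully resolved tone
#' specifications: each st value is classified ([classifyStLevel()]),
#' mapped to its tone parameters ([mapToneParams()]) and given its pitch
#' f0*2^(k/12) and onset trigger_time + i * inter_tone_ms (i = 0..5).
#'
#' @param set \code{"L1"} or \code{"L2"}.
#' @param triggerBeat single-row beat (list or data.frame with
#'   \code{index}, \code{r_time}).
#' @param st numeric vector of exactly 6 ST deviations (mV), in the
#'   set's fixed lead order ([scanLeadsL1()] / [scanLeadsL2()]), or a
#'   measurement data.frame with \code{lead} and \code{st} columns from
#'   which the set's leads are pulled.
#' @param cfg a [sonifyConfig()].
#' @return data.frame of 6 tone specs: \code{set}, \code{slot} (1-6),
#'   \code{lead}, \code{trigger_index}, \code{trigger_time},
#'   \code{onset} (s), \code{st} (mV), \code{level}, \code{semitone},
#'   \code{freq_hz}, \code{duration_ms}, \code{harmonics},
#'   \code{level_db}.
#' @export
#' @examples
#' buildScan("L2", list(index = 0, r_time = 1), rep(0, 6))
buildScan <- function(set, triggerBeat, st, cfg = sonifyConfig()) {
  set <- match.arg(set, c("L1", "L2"))
  leads <- if (set == "L1") scanLeadsL1() else scanLeadsL2()
  if (is.data.frame(st)) {
    idx <- match(leads, st$lead)
    if (anyNA(idx)) {
      stop("missing measurement for lead(s): ",
           paste(leads[is.na(idx)], collapse = ", "))
    }
    st <- st$st[idx]
  }
  st <- as.numeric(st)
  if (length(st) != 6L) stop("expected exactly 6 ST measurements, got ",
                             length(st))
  level <- classifyStLevel(st, cfg$cutoffs_mv)
  pars <- mapToneParams(level, cfg)
  data.frame(
    set = set, slot = 1:6, lead = leads,
    trigger_index = triggerBeat$index, trigger_time = triggerBeat$r_time,
    onset = triggerBeat$r_time + (0:5) * cfg$inter_tone_ms / 1000,
    st = st, level = as.character(level),
    semitone = pars$semitone,
    freq_hz = toneFreq(cfg$f0, pars$semitone),
    duration_ms = pars$duration_ms, harmonics = pars$harmonics,
    level_db = pars$level_db
  )
}

#' Build all scheduled scan events for a recording
#'
#' Composes [scheduleScans()] and [buildScan()]: schedules L1/L2 triggers
#' over the beat train and resolves each scan's six tones from the ST
#' measurements of its trigger beat (or the mean over the
#' \code{st_average_beats} beats ending at the trigger).
#'
#' @param beats beat table from [detectBeats()].
#' @param measurements measurement table from [measureSt()]; must cover
#'   every scan lead for every trigger beat.
#' @param cfg a [sonifyConfig()].
#' @return data.frame of tone specs (6 rows per scan, see [buildScan()]),
#'   ordered by onset.
#' @export
buildScanEvents <- function(beats, measurements, cfg = sonifyConfig()) {
  sched <- scheduleScans(beats, cfg)
  if (!nrow(sched)) {
    return(buildScan("L1", list(index = 0L, r_time = 0), rep(0, 6), cfg)[0, ])
  }
  events <- lapply(seq_len(nrow(sched)), function(i) {
    trig <- sched$trigger_index[i]
    span <- seq(trig - cfg$st_average_beats + 1L, trig)
    m <- measurements[measurements$beat %in% span, , drop = FALSE]
    m <- m[m$beat >= 0, , drop = FALSE]
    stBar <- tapply(m$st, m$lead, mean)
    mdf <- data.frame(lead = names(stBar), st = as.numeric(stBar))
    buildScan(sched$set[i],
              list(index = trig, r_time = sched$trigger_time[i]),
              mdf, cfg)
  })
  out <- do.call(rbind, events)
  out <- out[order(out$onset, out$slot), , drop = FALSE]
  rownames(out) <- NULL
  out
}
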