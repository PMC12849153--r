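#' Synthetic monitoring-scenario specification
#'
#' Describes a simulated 12-lead monitoring episode: an isoelectric
#' phase that, at \code{transition_time}, switches to the ST pattern of
#' the requested infarct class and severity. Defaults mirror a typical
#' simulated emergency scenario: 80 bpm, transition at 90 s.
#'
#' @param pattern \code{"normal"}, \code{"anterior_stemi"} or
#'   \code{"inferior_stemi"}.
#' @param severity \code{"weak"}, \code{"moderate"} or \code{"severe"}
#'   (ignored for \code{"normal"}).
#' @param heart_rate beats per minute (> 0), default 80.
#' @param transition_time seconds after start at which the ST pattern
#'   switches on (>= 0); a value beyond \code{total_duration} means the
#'   pattern never switches on within the record.
#' @param total_duration total record length, seconds.
#' @param noise_sd additive Gaussian noise standard deviation, mV.
#' @param seed integer RNG seed for the noise (reproducibility).
#' @param sampling_rate ECG sampling rate, samples/s.
#' @param rr_jitter_sd optional RR-interval jitter SD, seconds (0 =
#'   metronomic rhythm).
#' @param ramp_s optional linear onset ramp of the ST offset, seconds
#'   (0 = instantaneous switch, as on a scenario simulator).
#' @return list of class \code{"ScenarioSpec"}.
#' @export
#' @examples
#' scenarioSpec("anterior_stemi", "severe", total_duration = 120)
scenarioSpec <- function(pattern = c("normal", "anterior_stemi",
                                     "inferior_stemi"),
                         severity = c("moderate", "weak", "severe"),
                         heart_rate = 80, transition_time = 90,
                         total_duration = 180, noise_sd = 0, seed = 1L,
                         sampling_rate = 500, rr_jitter_sd = 0,
                         ramp_s = 0) {
  pattern <- match.arg(pattern)
  severity <- match.arg(severity)
  spec <- list(pattern = pattern, severity = severity,
               heart_rate = heart_rate, transition_time = transition_time,
               total_duration = total_duration, noise_sd = noise_sd,
               seed = as.integer(seed), sampling_rate = sampling_rate,
               rr_jitter_sd = rr_jitter_sd, ramp_s = ramp_s)
  stopifnot(heart_rate > 0, total_duration > 0,
            transition_time >= 0,
            noise_sd >= 0, sampling_rate > 0, rr_jitter_sd >= 0,
            ramp_s >= 0)
  class(spec) <- "ScenarioSpec"
  spec
}

#' @export
print.ScenarioSpec <- function(x, ...) {
  cat(sprintf("ScenarioSpec: %s%s, %g bpm, transition at %g s, %g s total, noise sd %g mV (seed %d)\n",
              x$pattern,
              if (x$pattern == "normal") "" else paste0(" (", x$severity, ")"),
              x$heart_rate, x$transition_time, x$total_duration,
              x$noise_sd, x$seed))
  invisible(x)
}

# elevation magnitude on affected leads per severity class, mV; chosen so
# weak falls in the moderate-elevation band (0.1 <= st <= 0.2) and
# moderate/severe exceed the strong-elevation cutoff (st > 0.2). The
# reciprocal factor is -0.6 so every injected value lies strictly inside
# a classification band (severe: -0.24, s2; moderate: -0.15, s1) rather
# than exactly on a cutoff, keeping the true class well defined.
.severityMv <- c(weak = 0.12, moderate = 0.25, severe = 0.40)
.reciprocalFactor <- -0.6

#' Per-lead ST-offset profile of an infarct pattern
#'
#' \code{"normal"}: all leads isoelectric. \code{"anterior_stemi"}:
#' elevation on the anteroseptal precordial leads V1-V4.
#' \code{"inferior_stemi"}: elevation on II, III, aVF with reciprocal
#' depression (-0.6 x the elevation) on I and aVL. Severity scales the
#' elevation: weak 0.12, moderate 0.25, severe 0.40 mV.
#'
#' @param pattern,severity as in [scenarioSpec()].
#' @return named numeric vector over the 12 acquired leads, mV.
#' @export
#' @examples
#' stProfile("anterior_stemi", "severe")["V2"]   # 0.40
#' stProfile("inferior_stemi", "moderate")["aVL"] # -0.15
stProfile <- function(pattern = c("normal", "anterior_stemi",
                                  "inferior_stemi"),
                      severity = c("moderate", "weak", "severe")) {
  pattern <- match.arg(pattern)
  severity <- match.arg(severity)
  st <- stats::setNames(numeric(12), ecgLeads())
  if (pattern == "normal") return(st)
  mag <- .severityMv[[severity]]
  if (pattern == "anterior_stemi") {
    st[c("V1", "V2", "V3", "V4")] <- mag
  } else {
    st[c("II", "III", "aVF")] <- mag
    st[c("I", "aVL")] <- .reciprocalFactor * mag
  }
  st
}

# P-QRS-T morphology as Gaussian bumps: per-wave centre (s, relative to
# the R peak), width (s, sd) and per-lead amplitude scale (mV)
.waveCenters <- c(P = -0.180, Q = -0.022, R = 0.000, S = 0.026, T = 0.320)
.waveWidths  <- c(P = 0.020,  Q = 0.006,  R = 0.010, S = 0.006, T = 0.045)
.leadWaveAmp <- matrix(c(
  #  P      Q      R      S      T
   0.08, -0.05,  0.70, -0.12,  0.25,   # I
   0.12, -0.08,  1.10, -0.18,  0.35,   # II
   0.05, -0.04,  0.50, -0.10,  0.15,   # III
  -0.10,  0.06, -0.90,  0.15, -0.30,   # aVR
   0.03, -0.03,  0.35, -0.08,  0.12,   # aVL
   0.09, -0.06,  0.80, -0.14,  0.25,   # aVF
   0.04,  0.00,  0.25, -0.80, -0.10,   # V1
   0.05,  0.00,  0.45, -0.90,  0.45,   # V2
   0.06, -0.02,  0.70, -0.60,  0.50,   # V3
   0.08, -0.05,  1.20, -0.40,  0.45,   # V4
   0.08, -0.06,  1.10, -0.25,  0.35,   # V5
   0.07, -0.05,  0.90, -0.18,  0.30),  # V6
  nrow = 12, byrow = TRUE,
  dimnames = list(c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6"),
                  c("P", "Q", "R", "S", "T")))

# smooth flat-topped ST-offset window: full amplitude from R+60 ms to
# R+380 ms with 20 ms raised-cosine edges; clear of both the PR baseline
# window and the next beat's PR segment at physiological rates
.stWindowShape <- function(tRel) {
  up0 <- 0.040; up1 <- 0.060; dn0 <- 0.380; dn1 <- 0.400
  w <- numeric(length(tRel))
  mid <- tRel >= up1 & tRel <= dn0
  w[mid] <- 1
  ru <- tRel > up0 & tRel < up1
  w[ru] <- 0.5 * (1 - cos(pi * (tRel[ru] - up0) / (up1 - up0)))
  rd <- tRel > dn0 & tRel < dn1
  w[rd] <- 0.5 * (1 + cos(pi * (tRel[rd] - dn0) / (dn1 - dn0)))
  w
}

#' Generate a synthetic 12-lead monitoring scenario
#'
#' Renders a metronomic beat train at the requested heart rate, each beat
#' drawn from a per-lead P-QRS-T template (sums of Gaussian bumps with a
#' small built-in amplitude table). For every beat whose R time is at or
#' after \code{transition_time}, the pattern's per-lead ST offset
#' ([stProfile()]) is added over a smooth flat-topped window between the
#' J point and the end of the T wave; beats before the transition carry
#' no offset. Optional additive Gaussian noise (seeded, reproducible)
#' and RR jitter.
#'
#' @param spec a [scenarioSpec()].
#' @param st_offsets optional named per-lead offset vector (mV)
#'   overriding [stProfile()] — useful for calibration experiments.
#' @return list with elements \code{recording} ([EcgRecording-class]) and
#'   \code{truth}: a list with \code{beats} (data.frame \code{index},
#'   \code{r_time}), \code{st_before} and \code{st_after} (named per-lead
#'   offsets, mV) and \code{transition_time}.
#' @export
#' @examples
#' out <- generateScenario(scenarioSpec("normal", total_duration = 10))
#' out$recording
#' head(out$truth$beats)
generateScenario <- function(spec, st_offsets = NULL) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  fs <- spec$sampling_rate
  n <- round(spec$total_duration * fs)
  tEdge <- 0.45                      # keep whole templates inside the record
  rr <- 60 / spec$heart_rate

  set.seed(spec$seed)
  rTimes <- seq(tEdge, spec$total_duration - tEdge, by = rr)
  if (spec$rr_jitter_sd > 0 && length(rTimes) > 1) {
    jit <- stats::rnorm(length(rTimes), 0, spec$rr_jitter_sd)
    rTimes <- sort(rTimes + jit)
    rTimes <- rTimes[rTimes > tEdge / 2 & rTimes < spec$total_duration - tEdge / 2]
  }

  stAfter <- if (is.null(st_offsets)) {
    stProfile(spec$pattern, spec$severity)
  } else {
    full <- stats::setNames(numeric(12), ecgLeads())
    full[normalizeLeadName(names(st_offsets))] <- st_offsets
    full
  }

  tAxis <- (seq_len(n) - 1) / fs
  sig <- matrix(0, nrow = n, ncol = 12, dimnames = list(NULL, ecgLeads()))
  span <- 0.44                       # template support, s, either side of R
  for (rt in rTimes) {
    i0 <- max(1L, floor((rt - span) * fs) + 1L)
    i1 <- min(n, ceiling((rt + span) * fs) + 1L)
    tRel <- tAxis[i0:i1] - rt
    shape <- vapply(names(.waveCenters), function(wv) {
      exp(-0.5 * ((tRel - .waveCenters[[wv]]) / .waveWidths[[wv]])^2)
    }, numeric(length(tRel)))
    beat <- shape %*% t(.leadWaveAmp)           # samples x 12
    elevated <- rt >= spec$transition_time
    if (elevated && any(stAfter != 0)) {
      scale <- 1
      if (spec$ramp_s > 0) {
        scale <- min(1, (rt - spec$transition_time) / spec$ramp_s)
      }
      stWin <- .stWindowShape(tRel)
      beat <- beat + outer(stWin, scale * stAfter)
    }
    sig[i0:i1, ] <- sig[i0:i1, ] + beat
  }
  if (spec$noise_sd > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0, spec$noise_sd),
                        nrow = n)
  }
  list(
    recording = EcgRecording(sig, samplingRate = fs),
    truth = list(
      beats = data.frame(index = seq_along(rTimes) - 1L, r_time = rTimes),
      st_before = stats::setNames(numeric(12), ecgLeads()),
      st_after = stAfter,
      transition_time = spec$transition_time
    )
  )
}

#' Write scenario ground truth as a delimited table
#'
#' Sidecar table for a generated scenario: one row per beat with its R
#' time and the injected per-lead ST offset active at that beat.
#'
#' @param truth the \code{truth} element of [generateScenario()] output.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  off <- vapply(truth$beats$r_time, function(rt) {
    if (rt >= truth$transition_time) truth$st_after else truth$st_before
  }, numeric(12))
  tab <- cbind(truth$beats, as.data.frame(t(off)))
  names(tab)[-(1:2)] <- paste0("st_", ecgLeads())
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
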