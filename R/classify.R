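#' The five ST-deviation levels
#'
#' Level labels in increasing order of ST deviation: s2 (strong
#' suppression), s1 (moderate suppression), IE (isoelectric), e1
#' (moderate elevation), e2 (strong elevation). Ordinals are -2..+2,
#' sign matching suppression/elevation and 0 for isoelectric.
#'
#' @return \code{stLevels()}: character vector of the 5 labels.
#'   \code{stLevelOrdinal()}: integer ordinal(s) for given label(s).
#' @param level character vector of level labels.
#' @export
#' @examples
#' stLevels()
#' stLevelOrdinal(c("s2", "IE", "e2"))
stLevels <- function() c("s2", "s1", "IE", "e1", "e2")

#' @rdname stLevels
#' @export
stLevelOrdinal <- function(level) {
  idx <- match(as.character(level), stLevels())
  if (anyNA(idx)) stop("unknown ST level label")
  idx - 3L
}

#' Classify ST deviation into one of five levels
#'
#' Applies the cutoff rule with thresholds at +/- inner and +/- outer mV
#' (defaults 0.1 and 0.2): st <= -0.2 is s2 (strongly suppressed);
#' -0.2 < st <= -0.1 is s1 (moderately suppressed); |st| < 0.1 is IE
#' (close to isoelectric); 0.1 <= st <= 0.2 is e1 (moderately elevated);
#' st > 0.2 is e2 (strongly elevated). The five intervals partition the
#' real line; boundary values 0.1 and 0.2 belong to e1, -0.1 and -0.2 to
#' s1 and s2 respectively, following the printed inequalities.
#'
#' @param st numeric vector of ST deviations, mV. Must be finite.
#' @param cutoffs two positive thresholds (inner, outer) in mV, or a
#'   \code{SonifyConfig} whose \code{cutoffs_mv} is used.
#' @return ordered factor with levels \code{stLevels()}, same length as
#'   \code{st}.
#' @export
#' @examples
#' classifyStLevel(c(-0.25, -0.15, 0, 0.15, 0.25))
#' classifyStLevel(c(-0.2, -0.1, 0.1, 0.2))  # boundary values
classifyStLevel <- function(st, cutoffs = c(0.1, 0.2)) {
  if (inherits(cutoffs, "SonifyConfig")) cutoffs <- cutoffs$cutoffs_mv
  stopifnot(length(cutoffs) == 2L, all(cutoffs > 0), cutoffs[1] < cutoffs[2])
  st <- as.numeric(st)
  if (any(!is.finite(st))) stop("st must be finite")
  inner <- cutoffs[1]; outer <- cutoffs[2]
  lab <- ifelse(st <= -outer, "s2",
         ifelse(st <= -inner, "s1",
         ifelse(st <  inner,  "IE",
         ifelse(st <= outer,  "e1", "e2"))))
  factor(lab, levels = stLevels(), ordered = TRUE)
}

#' The tone-parameter mapping table
#'
#' One row per ST level giving the synthesis parameters of its scan tone:
#' pitch offset from the QRS tone in semitones, duration in ms, number of
#' harmonic partials (brightness), and level in dB relative to the IE
#' tone. Defaults: semitones (-8, -5, 0, 4, 7), durations (100, 80, 50,
#' 80, 100) ms, harmonics (3, 3, 1, 3, 3), levels (15, 5, 0, 5, 15) dB
#' for (s2, s1, IE, e1, e2) — extreme deviations are louder, longer and
#' brighter so they perceptually stand out.
#'
#' @param cfg a [sonifyConfig()].
#' @return data.frame with columns \code{level}, \code{ordinal},
#'   \code{semitone}, \code{duration_ms}, \code{harmonics},
#'   \code{level_db}.
#' @export
#' @examples
#' toneMap(sonifyConfig())
toneMap <- function(cfg = sonifyConfig()) {
  stopifnot(inherits(cfg, "SonifyConfig"))
  data.frame(
    level = factor(stLevels(), levels = stLevels(), ordered = TRUE),
    ordinal = -2:2,
    semitone = cfg$semitones,
    duration_ms = cfg$durations_ms,
    harmonics = cfg$harmonics,
    level_db = cfg$levels_db
  )
}

#' Look up the tone parameters for ST level(s)
#'
#' Pure table lookup into [toneMap()].
#'
#' @param level ST level label(s) (see [stLevels()]) or factor.
#' @param cfg a [sonifyConfig()].
#' @return data.frame with one row per element of \code{level} and the
#'   columns of [toneMap()].
#' @export
#' @examples
#' mapToneParams("e2")   # 7 semitones, 100 ms, 3 harmonics, 15 dB
#' mapToneParams("IE")   # 0 semitones, 50 ms, 1 harmonic, 0 dB
mapToneParams <- function(level, cfg = sonifyConfig()) {
  tm <- toneMap(cfg)
  idx <- match(as.character(level), as.character(tm$level))
  if (anyNA(idx)) stop("unknown ST level label")
  out <- tm[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
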