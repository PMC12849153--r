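#' Sonification configuration
#'
#' Bundles every tunable parameter of the grouped-lead-scan sonification:
#' the reference (QRS) pitch, the classification cutoffs, the five-level
#' tone-parameter map, the scan schedule, synthesis settings and the
#' ST-measurement windows. Defaults reproduce the published design.
#'
#' @param f0 reference pitch p0 of the QRS tone, Hz. All scan tones are
#'   pitched relative to it by whole semitones: f(k) = f0 * 2^(k/12).
#' @param cutoffs_mv two positive thresholds (inner, outer) in mV.
#'   Classification: st <= -outer is s2; -outer < st <= -inner is s1;
#'   |st| < inner is IE; inner <= st <= outer is e1; st > outer is e2.
#' @param semitones,durations_ms,harmonics,levels_db the tone-parameter
#'   map, one entry per level in order (s2, s1, IE, e1, e2).
#' @param inter_tone_ms spacing between the six tones of one scan, ms.
#' @param scan_period_beats an L1 scan fires every this-many beats.
#' @param l2_offset_beats the L2 scan fires this many beats after its L1.
#' @param sample_rate audio sample rate, samples/s.
#' @param attack_ms linear attack ramp applied to every tone (declick).
#' @param qrs_tone_ms duration of the QRS reference beep.
#' @param qrs_level_db level of the QRS beep relative to an IE tone.
#' @param curvature_max,curvature_min,curvature_slope,curvature_st_cap
#'   fade-out curvature law gamma(|st|) = max(curvature_min,
#'   curvature_max - curvature_slope * min(|st|, curvature_st_cap));
#'   larger gamma = steeper fade, so tones for extreme st decay slower.
#' @param j_offset_ms J-point location after the R peak, ms.
#' @param st_delay_ms ST measurement point after the J-point, ms (J+60).
#' @param st_window_ms averaging window width centred on the measurement
#'   point, ms.
#' @param baseline_window_ms two offsets (ms, relative to R) delimiting
#'   the PR-segment baseline window.
#' @param st_average_beats number of consecutive beats averaged into the
#'   st value fed to a scan (1 = the trigger beat alone).
#'
#' @return A list of class \code{"SonifyConfig"}.
#' @export
#' @examples
#' cfg <- sonifyConfig()
#' cfg$f0
#' toneMap(cfg)
sonifyConfig <- function(f0 = 554,
                         cutoffs_mv = c(0.1, 0.2),
                         semitones = c(-8, -5, 0, 4, 7),
                         durations_ms = c(100, 80, 50, 80, 100),
                         harmonics = c(3, 3, 1, 3, 3),
                         levels_db = c(15, 5, 0, 5, 15),
                         inter_tone_ms = 120,
                         scan_period_beats = 8,
                         l2_offset_beats = 2,
                         sample_rate = 44100,
                         attack_ms = 5,
                         qrs_tone_ms = 60,
                         qrs_level_db = 0,
                         curvature_max = 3,
                         curvature_min = 0.5,
                         curvature_slope = 5,
                         curvature_st_cap = 0.4,
                         j_offset_ms = 80,
                         st_delay_ms = 60,
                         st_window_ms = 20,
                         baseline_window_ms = c(-120, -40),
                         st_average_beats = 1) {
  cfg <- list(
    f0 = f0, cutoffs_mv = cutoffs_mv, semitones = semitones,
    durations_ms = durations_ms, harmonics = harmonics,
    levels_db = levels_db, inter_tone_ms = inter_tone_ms,
    scan_period_beats = scan_period_beats,
    l2_offset_beats = l2_offset_beats, sample_rate = sample_rate,
    attack_ms = attack_ms, qrs_tone_ms = qrs_tone_ms,
    qrs_level_db = qrs_level_db,
    curvature_max = curvature_max, curvature_min = curvature_min,
    curvature_slope = curvature_slope, curvature_st_cap = curvature_st_cap,
    j_offset_ms = j_offset_ms, st_delay_ms = st_delay_ms,
    st_window_ms = st_window_ms, baseline_window_ms = baseline_window_ms,
    st_average_beats = st_average_beats)
  class(cfg) <- "SonifyConfig"
  validateSonifyConfig(cfg)
  cfg
}

validateSonifyConfig <- function(cfg) {
  stopifnot(
    cfg$f0 > 0,
    length(cfg$cutoffs_mv) == 2L, all(cfg$cutoffs_mv > 0),
    cfg$cutoffs_mv[1] < cfg$cutoffs_mv[2],
    length(cfg$semitones) == 5L, length(cfg$durations_ms) == 5L,
    length(cfg$harmonics) == 5L, length(cfg$levels_db) == 5L,
    all(cfg$durations_ms > 0), all(cfg$harmonics >= 1),
    cfg$inter_tone_ms > 0, cfg$scan_period_beats >= 1,
    cfg$l2_offset_beats >= 0, cfg$sample_rate > 0,
    cfg$attack_ms >= 0, cfg$qrs_tone_ms > 0,
    cfg$st_window_ms > 0,
    length(cfg$baseline_window_ms) == 2L,
    cfg$baseline_window_ms[1] < cfg$baseline_window_ms[2],
    cfg$st_average_beats >= 1
  )
  invisible(cfg)
}

#' @export
print.SonifyConfig <- function(x, ...) {
  cat("SonifyConfig\n")
  cat(sprintf("  f0 = %g Hz; cutoffs = +/-%g, +/-%g mV\n",
              x$f0, x$cutoffs_mv[1], x$cutoffs_mv[2]))
  cat("  tone map (s2 s1 IE e1 e2):\n")
  cat("    semitones: ", paste(x$semitones, collapse = " "), "\n")
  cat("    duration ms:", paste(x$durations_ms, collapse = " "), "\n")
  cat("    harmonics: ", paste(x$harmonics, collapse = " "), "\n")
  cat("    level dB:  ", paste(x$levels_db, collapse = " "), "\n")
  cat(sprintf("  schedule: L1 every %d beats, L2 +%d beats, tones every %g ms\n",
              x$scan_period_beats, x$l2_offset_beats, x$inter_tone_ms))
  invisible(x)
}

#' Read / write a run configuration file
#'
#' Run configurations are YAML key/value files whose keys are exactly the
#' arguments of [sonifyConfig()]; unknown keys are rejected so that typos
#' fail loudly. Values present in the file override the defaults.
#'
#' @param path YAML file path.
#' @param cfg a \code{SonifyConfig} to serialize.
#' @return \code{readRunConfig}: a \code{SonifyConfig};
#'   \code{writeRunConfig}: \code{path}, invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sonifyConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(known, collapse = ", "))
  }
  do.call(sonifyConfig, vals)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "SonifyConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
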