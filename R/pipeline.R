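#' Sonify an ECG recording end to end
#'
#' The full monitoring chain on an in-memory recording: beat detection
#' (or supplied annotations), per-beat per-lead ST measurement, level
#' classification, scan scheduling and audio rendering.
#'
#' @param rec an [EcgRecording-class].
#' @param cfg a [sonifyConfig()].
#' @param annotations optional known R times (s), bypassing detection.
#' @return list with \code{audio} ([AudioBuffer-class]), \code{tones}
#'   (the scan-event table, see [buildScanEvents()]), \code{beats} and
#'   \code{measurements}.
#' @export
sonifyRecording <- function(rec, cfg = sonifyConfig(), annotations = NULL) {
  stopifnot(is(rec, "EcgRecording"), inherits(cfg, "SonifyConfig"))
  beats <- detectBeats(rec, annotations = annotations)
  beats <- trimEdgeBeats(beats, rec, cfg)
  meas <- if (nrow(beats)) measureSt(rec, beats, cfg = cfg) else {
    data.frame(beat = integer(0), r_time = numeric(0),
               lead = character(0), st = numeric(0))
  }
  tones <- buildScanEvents(beats, meas, cfg)
  audio <- renderAudio(tones, beats, cfg, totalDuration = duration(rec))
  list(audio = audio, tones = tones, beats = beats, measurements = meas)
}

# drop beats whose measurement windows fall outside the record
trimEdgeBeats <- function(beats, rec, cfg) {
  if (!nrow(beats)) return(beats)
  lo <- -min(0, cfg$baseline_window_ms[1] / 1000)
  hi <- (cfg$j_offset_ms + cfg$st_delay_ms + cfg$st_window_ms / 2) / 1000
  keep <- beats$r_time >= lo & beats$r_time + hi <= duration(rec)
  beats <- beats[keep, , drop = FALSE]
  beats$index <- seq_len(nrow(beats)) - 1L
  rownames(beats) <- NULL
  beats
}

#' Generate a scenario and render its sonification
#'
#' Composes [generateScenario()] with [sonifyRecording()]: scans
#' triggered before the transition contain only isoelectric tones, and
#' the first precordial (L2) scan after it carries the elevated levels
#' on the affected leads.
#'
#' @param spec a [scenarioSpec()].
#' @param cfg a [sonifyConfig()].
#' @return as [sonifyRecording()], plus \code{recording} and
#'   \code{truth}.
#' @export
endToEndScenarioAudio <- function(spec, cfg = sonifyConfig()) {
  out <- generateScenario(spec)
  res <- sonifyRecording(out$recording, cfg)
  c(res, out)
}

#' Write a scan-event log
#'
#' Machine-readable per-tone log (tab-separated with header): trigger
#' time, scan set, lead, measured st (mV), level, semitone offset and
#' tone frequency.
#'
#' @param tones scan-event table from [buildScanEvents()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEventLog <- function(tones, path) {
  log <- data.frame(time_s = tones$trigger_time, set = tones$set,
                    lead = tones$lead, st_mv = tones$st,
                    level = tones$level, semitone = tones$semitone,
                    freq_hz = tones$freq_hz)
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sonify an ECG file to a WAV file (command-level entry point)
#'
#' Reads an ECG, runs the sonification chain and writes the WAV plus a
#' scan-event log \code{<output minus .wav>_events.tsv}. Nothing is
#' written if any stage fails.
#'
#' @param input ECG path (see [readEcg()]).
#' @param output WAV output path.
#' @param config optional run-configuration YAML ([readRunConfig()]).
#' @param samplingRate optional sampling rate for headerless tables.
#' @param cfg alternatively, a ready [sonifyConfig()].
#' @return (invisibly) the [sonifyRecording()] result, with
#'   \code{$event_log} naming the log file.
#' @export
runSonify <- function(input, output, config = NULL, samplingRate = NULL,
                      cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- if (is.null(config)) sonifyConfig() else readRunConfig(config)
  }
  rec <- readEcg(input, samplingRate = samplingRate)
  res <- sonifyRecording(rec, cfg)
  writeWav(res$audio, output)
  logPath <- paste0(sub("\\.wav$", "", output), "_events.tsv")
  writeEventLog(res$tones, logPath)
  res$event_log <- logPath
  invisible(res)
}

#' Simulate a scenario and write ECG, ground truth and WAV
#'
#' @param outputPrefix paths are \code{<prefix>_ecg.csv},
#'   \code{<prefix>_truth.tsv}, \code{<prefix>.wav} (and the event log
#'   \code{<prefix>_events.tsv}).
#' @param pattern,severity,heart_rate,transition_time,total_duration,noise_sd,seed
#'   scenario parameters, see [scenarioSpec()].
#' @param cfg a [sonifyConfig()].
#' @return (invisibly) named character vector of written paths.
#' @export
runSimulate <- function(outputPrefix, pattern = "normal",
                        severity = "moderate", heart_rate = 80,
                        transition_time = 90, total_duration = 180,
                        noise_sd = 0, seed = 1L, cfg = sonifyConfig()) {
  spec <- scenarioSpec(pattern, severity, heart_rate = heart_rate,
                       transition_time = transition_time,
                       total_duration = total_duration,
                       noise_sd = noise_sd, seed = seed)
  res <- endToEndScenarioAudio(spec, cfg)
  paths <- c(ecg = paste0(outputPrefix, "_ecg.csv"),
             truth = paste0(outputPrefix, "_truth.tsv"),
             wav = paste0(outputPrefix, ".wav"),
             events = paste0(outputPrefix, "_events.tsv"))
  writeEcg(res$recording, paths[["ecg"]])
  writeGroundTruth(res$truth, paths[["truth"]])
  writeWav(res$audio, paths[["wav"]])
  writeEventLog(res$tones, paths[["events"]])
  invisible(paths)
}

#' Classify every beat and lead of an ECG file
#'
#' Prints (or writes) the per-beat, per-lead table of measured ST
#' deviation and its level: beats x (12 acquired leads + negAVR) rows.
#'
#' @param input ECG path.
#' @param output optional TSV path; when NULL the table is returned.
#' @param config,samplingRate,cfg as in [runSonify()].
#' @param derivedLead include the derived negAVR rows (default FALSE:
#'   exactly the 12 acquired leads).
#' @return data.frame with \code{beat}, \code{r_time}, \code{lead},
#'   \code{st_mv}, \code{level} (invisibly when written to file).
#' @export
runClassify <- function(input, output = NULL, config = NULL,
                        samplingRate = NULL, cfg = NULL,
                        derivedLead = FALSE) {
  if (is.null(cfg)) {
    cfg <- if (is.null(config)) sonifyConfig() else readRunConfig(config)
  }
  rec <- readEcg(input, samplingRate = samplingRate)
  beats <- trimEdgeBeats(detectBeats(rec), rec, cfg)
  leads <- if (derivedLead) c(ecgLeads(), "negAVR") else ecgLeads()
  meas <- measureSt(rec, beats, leads = leads, cfg = cfg)
  tab <- data.frame(beat = meas$beat, r_time = meas$r_time,
                    lead = meas$lead, st_mv = meas$st,
                    level = as.character(classifyStLevel(meas$st,
                                                         cfg$cutoffs_mv)))
  if (!is.null(output)) {
    utils::write.table(tab, output, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(tab))
  }
  tab
}
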