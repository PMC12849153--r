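#' Read a 12-lead ECG from file
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{\code{"table"}}{delimited text: a header row of lead names,
#'     one comma-separated column per lead, samples in mV. An optional
#'     leading \code{time_s} column carries the time axis; otherwise the
#'     sampling rate comes from the \code{samplingRate} argument or from
#'     a YAML sidecar \code{<path>.yaml} with key \code{sampling_rate}.}
#'   \item{\code{"record"}}{a physiological waveform record: a plain-text
#'     header \code{<record>.hea} naming the signal file, format, gain
#'     and lead names, plus an interleaved 16-bit little-endian signal
#'     file. \code{path} is the header file (or its basename).}
#' }
#' All 12 standard leads must be present (any column order, case
#' tolerated); amplitudes are converted to mV via the per-signal gain for
#' records.
#'
#' @param path input file (table: the CSV; record: the \code{.hea} file).
#' @param format \code{"auto"} (by extension), \code{"table"} or
#'   \code{"record"}.
#' @param samplingRate samples/second; required for tables without a
#'   \code{time_s} column or sidecar.
#' @return An [EcgRecording-class].
#' @export
#' @seealso [writeEcg()]
readEcg <- function(path, format = c("auto", "table", "record"),
                    samplingRate = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path)) "record" else "table"
  }
  if (format == "record") readEcgRecord(path) else {
    readEcgTable(path, samplingRate)
  }
}

readEcgTable <- function(path, samplingRate = NULL) {
  if (!file.exists(path)) stop("ECG file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  hasTime <- "time_s" %in% names(tab)
  if (hasTime) {
    tvec <- tab[["time_s"]]
    tab <- tab[, setdiff(names(tab), "time_s"), drop = FALSE]
    dt <- diff(tvec)
    if (length(dt) < 1L || any(dt <= 0)) stop("non-increasing time axis")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
      stop("non-uniform sampling in time_s column")
    }
    fsTime <- 1 / stats::median(dt)
    if (is.null(samplingRate)) samplingRate <- fsTime
  }
  if (is.null(samplingRate)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      sc <- yaml::read_yaml(sidecar)
      samplingRate <- sc[["sampling_rate"]]
    }
  }
  if (is.null(samplingRate)) {
    stop("sampling rate unknown: provide samplingRate, a time_s column, ",
         "or a '", basename(path), ".yaml' sidecar with key sampling_rate")
  }
  missing <- tryCatch(setdiff(ecgLeads(), normalizeLeadName(names(tab))),
                      error = function(e) stop("unrecognized column name in ",
                                               path, ": ", conditionMessage(e)))
  if (length(missing)) {
    stop("missing ECG lead(s): ", paste(missing, collapse = ", "))
  }
  EcgRecording(as.matrix(tab), samplingRate = samplingRate)
}

# --- waveform record (header + 16-bit signal file) ---------------------

readEcgRecord <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("record header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in header")
  if (nsig < 1L || length(lines) < 1L + nsig) stop("malformed record header")
  sigspec <- lapply(lines[2:(1 + nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    # filename format gain(baseline)/units adcres adczero initval cks bs desc
    gainfield <- f[3]
    units <- sub("^[^/]*/?", "", gainfield)
    if (nzchar(units) && toupper(units) != "MV") {
      stop("signal units not convertible to mV: ", units)
    }
    gb <- sub("/.*$", "", gainfield)
    baseline <- 0
    if (grepl("\\(", gb)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gb))
      gb <- sub("\\(.*$", "", gb)
    }
    gain <- as.numeric(gb)
    if (!is.finite(gain) || gain == 0) gain <- 200  # format default adu/mV
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         desc = f[length(f)])
  })
  fmts <- unique(vapply(sigspec, `[[`, "", "format"))
  if (!identical(fmts, "16")) {
    stop("unsupported signal format(s): ", paste(fmts, collapse = ", "),
         " (only format 16 is supported)")
  }
  datfile <- file.path(dirname(hea), sigspec[[1]]$file)
  if (!file.exists(datfile)) stop("signal file not found: ", datfile)
  raw <- readBin(datfile, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp + nsig)
  if (length(raw) < nsig * nsamp) stop("signal file shorter than header claims")
  adc <- matrix(raw[seq_len(nsig * nsamp)], ncol = nsig, byrow = TRUE)
  mv <- vapply(seq_len(nsig), function(j) {
    (adc[, j] - sigspec[[j]]$baseline) / sigspec[[j]]$gain
  }, numeric(nsamp))
  colnames(mv) <- vapply(sigspec, `[[`, "", "desc")
  missing <- tryCatch(setdiff(ecgLeads(), normalizeLeadName(colnames(mv))),
                      error = function(e) stop("unrecognized lead in header: ",
                                               conditionMessage(e)))
  if (length(missing)) {
    stop("missing ECG lead(s): ", paste(missing, collapse = ", "))
  }
  EcgRecording(mv, samplingRate = fs)
}

#' Write a 12-lead ECG to file
#'
#' Writes the dialects read by [readEcg()]. Tables get a leading
#' \code{time_s} column so they are self-describing; records are written
#' as \code{<prefix>.hea} + \code{<prefix>.dat} (format 16, gain 1000
#' adu/mV, so amplitudes are quantized to 0.001 mV).
#'
#' @param rec an [EcgRecording-class].
#' @param path output path: the CSV file for tables, the record prefix or
#'   \code{.hea} path for records.
#' @param format \code{"table"} or \code{"record"}.
#' @param timeColumn include the \code{time_s} column (tables only).
#' @return the main written path, invisibly.
#' @export
writeEcg <- function(rec, path, format = c("table", "record"),
                     timeColumn = TRUE) {
  stopifnot(is(rec, "EcgRecording"))
  format <- match.arg(format)
  if (format == "table") {
    tab <- as.data.frame(rec@signals)
    if (timeColumn) {
      tab <- cbind(time_s = (seq_len(nrow(tab)) - 1) / rec@samplingRate, tab)
    } else {
      yaml::write_yaml(list(sampling_rate = rec@samplingRate),
                       paste0(path, ".yaml"))
    }
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(path))
  }
  prefix <- sub("\\.hea$", "", path)
  recname <- basename(prefix)
  gain <- 1000
  adc <- round(rec@signals * gain)
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"
  cks <- vapply(seq_len(ncol(adc)), function(j) {
    s <- sum(as.numeric(adc[, j])) %% 65536
    as.integer(if (s > 32767) s - 65536 else s)
  }, integer(1))
  hdr <- c(
    sprintf("%s %d %g %d", recname, ncol(adc), rec@samplingRate, nrow(adc)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d %d 0 %s",
            recname, gain, adc[1, ], cks, colnames(adc))
  )
  writeLines(hdr, paste0(prefix, ".hea"))
  writeBin(as.integer(t(adc)), paste0(prefix, ".dat"), size = 2L,
           endian = "little")
  invisible(paste0(prefix, ".hea"))
}

#' Derive the inverted-aVR lead
#'
#' Returns the sample-wise negation of lead aVR (the derived lead
#' \code{negAVR}), which completes the Cabrera ordering of the limb
#' leads used by scan list L1.
#'
#' @param rec an [EcgRecording-class] containing lead aVR.
#' @return numeric vector, mV.
#' @export
#' @examples
#' rec <- generateScenario(scenarioSpec("normal", total_duration = 5))$recording
#' all.equal(deriveNegAVR(rec), -leadSignal(rec, "aVR"))
deriveNegAVR <- function(rec) {
  stopifnot(is(rec, "EcgRecording"))
  -rec@signals[, "aVR"]
}
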