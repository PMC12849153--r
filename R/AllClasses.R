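#' @import methods
NULL

#' Canonical 12-lead names
#'
#' The twelve acquired leads of the standard ECG, in conventional order:
#' limb leads, augmented leads, precordial leads. The derived lead
#' \code{negAVR} (aVR with inverted polarity, completing the Cabrera
#' sequence) is never acquired and is obtained with [deriveNegAVR()].
#'
#' @return Character vector of the 12 acquired lead names.
#' @export
#' @examples
#' ecgLeads()
ecgLeads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Cabrera-ordered limb-lead scan list (L1) and precordial scan list (L2)
#'
#' Lead scan L1 walks the frontal plane along the Cabrera circle
#' (aVL, I, -aVR, II, aVF, III); L2 walks the chest wall V1..V6.
#' \code{negAVR} denotes inverted aVR.
#'
#' @return Character vector of 6 lead names.
#' @export
#' @examples
#' scanLeadsL1()
#' scanLeadsL2()
scanLeadsL1 <- function() c("aVL", "I", "negAVR", "II", "aVF", "III")

#' @rdname scanLeadsL1
#' @export
scanLeadsL2 <- function() c("V1", "V2", "V3", "V4", "V5", "V6")

# normalize user-supplied lead labels to canonical names
normalizeLeadName <- function(x) {
  canon <- c(ecgLeads(), "negAVR")
  idx <- match(toupper(x), toupper(canon))
  bad <- is.na(idx)
  if (any(bad)) {
    stop("unknown ECG lead name(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  canon[idx]
}

#' EcgRecording: a multichannel ECG waveform
#'
#' S4 container for a uniformly sampled 12-lead ECG. Signals are stored as
#' a numeric matrix (rows = samples, columns = leads, amplitudes in mV)
#' with a positive sampling rate in samples per second. All readers and
#' the synthetic generator produce this class.
#'
#' @slot signals numeric matrix, one column per acquired lead, mV.
#' @slot samplingRate sampling rate in samples/second (> 0).
#'
#' @seealso [readEcg()], [generateScenario()], [leadSignal()]
#' @export
setClass("EcgRecording",
  representation(signals = "matrix", samplingRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0) {
      msg <- c(msg, "samplingRate must be a single positive number")
    }
    if (!is.numeric(object@signals)) {
      msg <- c(msg, "signals must be a numeric matrix")
    }
    cn <- colnames(object@signals)
    if (is.null(cn) || !setequal(cn, ecgLeads()) || anyDuplicated(cn)) {
      msg <- c(msg, "signals must have exactly the 12 standard leads as columns")
    }
    if ("negAVR" %in% cn) {
      msg <- c(msg, "negAVR is a derived lead and must not be stored")
    }
    if (any(!is.finite(object@signals))) {
      msg <- c(msg, "signals must be finite")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an EcgRecording
#'
#' @param signals numeric matrix (samples x leads, mV) with the 12
#'   standard lead names as column names, in any order.
#' @param samplingRate samples per second.
#' @return An [EcgRecording-class] object with leads in canonical order.
#' @export
#' @examples
#' sig <- matrix(0, nrow = 500, ncol = 12, dimnames = list(NULL, ecgLeads()))
#' rec <- EcgRecording(sig, samplingRate = 250)
#' duration(rec)
EcgRecording <- function(signals, samplingRate) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  colnames(signals) <- normalizeLeadName(colnames(signals))
  missing <- setdiff(ecgLeads(), colnames(signals))
  if (length(missing)) {
    stop("missing ECG lead(s): ", paste(missing, collapse = ", "))
  }
  new("EcgRecording", signals = signals[, ecgLeads(), drop = FALSE],
      samplingRate = as.numeric(samplingRate))
}

#' AudioBuffer: single-channel rendered audio
#'
#' S4 container for mono audio samples in [-1, 1] at a fixed sample rate.
#'
#' @slot samples numeric vector of samples.
#' @slot sampleRate samples per second (> 0).
#' @seealso [renderAudio()], [writeWav()]
#' @export
setClass("AudioBuffer",
  representation(samples = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0) {
      msg <- c(msg, "sampleRate must be a single positive number")
    }
    if (any(!is.finite(object@samples))) {
      msg <- c(msg, "samples must be finite")
    }
    if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-12) {
      msg <- c(msg, "samples must lie in [-1, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AudioBuffer
#' @param samples numeric vector in [-1, 1].
#' @param sampleRate samples per second.
#' @return An [AudioBuffer-class] object.
#' @export
AudioBuffer <- function(samples, sampleRate) {
  new("AudioBuffer", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate))
}
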