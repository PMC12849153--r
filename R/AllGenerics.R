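#' Accessors for EcgRecording and AudioBuffer
#'
#' @param object an [EcgRecording-class] or [AudioBuffer-class].
#' @return \code{samplingRate}/\code{sampleRate}: samples per second.
#'   \code{nSamples}: number of samples per channel. \code{duration}:
#'   seconds. \code{leadNames}: lead labels. \code{audioSamples}: the raw
#'   sample vector.
#' @name ecg-accessors
NULL

#' @rdname ecg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ecg-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname ecg-accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname ecg-accessors
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))

#' @rdname ecg-accessors
#' @export
setGeneric("audioSamples", function(object) standardGeneric("audioSamples"))

#' @rdname ecg-accessors
setMethod("samplingRate", "EcgRecording", function(object) object@samplingRate)

#' @rdname ecg-accessors
setMethod("samplingRate", "AudioBuffer", function(object) object@sampleRate)

#' @rdname ecg-accessors
setMethod("nSamples", "EcgRecording", function(object) nrow(object@signals))

#' @rdname ecg-accessors
setMethod("nSamples", "AudioBuffer", function(object) length(object@samples))

#' @rdname ecg-accessors
setMethod("duration", "EcgRecording",
          function(object) nrow(object@signals) / object@samplingRate)

#' @rdname ecg-accessors
setMethod("duration", "AudioBuffer",
          function(object) length(object@samples) / object@sampleRate)

#' @rdname ecg-accessors
setMethod("leadNames", "EcgRecording", function(object) colnames(object@signals))

#' @rdname ecg-accessors
setMethod("audioSamples", "AudioBuffer", function(object) object@samples)

#' Extract one lead's samples
#'
#' Returns the sample vector (mV) of an acquired lead, or of the derived
#' lead \code{negAVR} (inverted aVR).
#'
#' @param object an [EcgRecording-class].
#' @param lead lead name (one of [ecgLeads()] or \code{"negAVR"}).
#' @return numeric vector, mV.
#' @export
setGeneric("leadSignal", function(object, lead) standardGeneric("leadSignal"))

#' @rdname leadSignal
setMethod("leadSignal", "EcgRecording", function(object, lead) {
  lead <- normalizeLeadName(lead)
  stopifnot(length(lead) == 1L)
  if (lead == "negAVR") return(-object@signals[, "aVR"])
  object@signals[, lead]
})

setMethod("show", "EcgRecording", function(object) {
  cat("EcgRecording:", ncol(object@signals), "leads,",
      nrow(object@signals), "samples @", object@samplingRate, "Hz",
      sprintf("(%.2f s)\n", duration(object)))
  cat("  leads:", paste(colnames(object@signals), collapse = " "), "\n")
  rng <- range(object@signals)
  cat(sprintf("  amplitude range: [%.3f, %.3f] mV\n", rng[1], rng[2]))
})

setMethod("show", "AudioBuffer", function(object) {
  cat("AudioBuffer:", length(object@samples), "samples @",
      object@sampleRate, "Hz", sprintf("(%.3f s)", duration(object)))
  if (length(object@samples)) {
    cat(sprintf(", peak %.3f", max(abs(object@samples))))
  }
  cat("\n")
})
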