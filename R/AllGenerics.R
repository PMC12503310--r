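#' @include AllClasses.R
NULL

#' Accessors for entrainEEG objects
#'
#' `eegSamples()` returns the channels x time matrix, `samplingRate()` the
#' rate in Hz, `channelLabels()` the electrode names, `syncTrace()` the light
#' sync trace and `recordingMetadata()` the metadata list of an
#' [EEGRecording-class]. `segmentBounds()` returns the half-open 0-based
#' `[start, end)` intervals of a [SessionSegments-class] as a data frame.
#' `plvValues()` extracts the numeric matrix of a [PLVMatrix-class].
#'
#' @param x an entrainEEG object.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("syncTrace", function(x) standardGeneric("syncTrace"))

#' @rdname accessors
#' @export
setGeneric("recordingMetadata", function(x) standardGeneric("recordingMetadata"))

#' @rdname accessors
#' @export
setGeneric("segmentBounds", function(x) standardGeneric("segmentBounds"))

#' @rdname accessors
#' @export
setGeneric("plvValues", function(x) standardGeneric("plvValues"))

#' @rdname accessors
setMethod("eegSamples", "EEGRecording", function(x) x@samples)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @rdname accessors
setMethod("syncTrace", "EEGRecording", function(x) x@sync)

#' @rdname accessors
setMethod("recordingMetadata", "EEGRecording", function(x) x@metadata)

#' @rdname accessors
setMethod("segmentBounds", "SessionSegments", function(x) {
  data.frame(
    condition = .SEGMENT_CONDITIONS,
    start = unname(x@start),
    end = unname(x@end),
    duration_s = unname((x@end - x@start) / x@samplingRate)
  )
})

#' @rdname accessors
setMethod("plvValues", "PLVMatrix", function(x) x@values)

setMethod("show", "EEGRecording", function(object) {
  md <- object@metadata
  cat(sprintf(
    "EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
    nrow(object@samples), ncol(object@samples),
    ncol(object@samples) / object@samplingRate, object@samplingRate
  ))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
  if (length(md))
    cat(sprintf(
      "  subject: %s | group: %s | day: %s\n",
      md$subject %||% "?", md$group %||% "?", md$day %||% "?"
    ))
  cat(sprintf("  sync trace: %s\n",
              if (length(object@sync)) "present" else "absent"))
})

setMethod("show", "SessionSegments", function(object) {
  cat("SessionSegments (half-open, 0-based samples):\n")
  print(segmentBounds(object), row.names = FALSE)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d channels at %g Hz, stimulus %g Hz (duty %.2f)\n",
    object@nChannels, object@samplingRate, object@stimulusFrequency,
    object@dutyCycle
  ))
  cat(sprintf("  segments (s): %s\n",
              paste(sprintf("%s=%g", names(object@segmentDurations),
                            object@segmentDurations), collapse = ", ")))
  cat(sprintf(
    "  amplitudes (uV): %s | kappa=%g | seed=%d\n",
    paste(signif(object@entrainmentAmplitudes, 3), collapse = ", "),
    object@jitterKappa, object@seed
  ))
})

setMethod("show", "SimTruth", function(object) {
  off <- object@expectedPlv[upper.tri(object@expectedPlv)]
  cat(sprintf(
    "SimTruth: expected band fraction %.4g-%.4g; expected off-diagonal PLV %.4g\n",
    min(object@expectedBandFraction), max(object@expectedBandFraction),
    if (length(off)) off[1] else NA_real_
  ))
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf(
    "SpectralEstimate [%s]: %d channels, %g-%g Hz at %.3g Hz resolution (%d windows)\n",
    object@segmentLabel, nrow(object@power), min(object@frequencies),
    max(object@frequencies), object@resolution, object@nWindows
  ))
})

setMethod("show", "StftResult", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "StftResult: %d frames x %d frequencies x %d channels (window %g s, hop %g s)\n",
    d[1], d[2], d[3], object@windowS, object@hopS
  ))
})

setMethod("show", "PLVMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "%sPLVMatrix [%s, day %s]: %d channels, mean off-diagonal %.3f (N=%d)\n",
    if (object@normalized) "normalized " else "", object@condition,
    format(object@day), nrow(object@values), mean(off), object@nSamples
  ))
})
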