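#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a single EEG session: a channels-by-time sample matrix in
#' microvolts, the sampling rate, 10-20 channel labels, the light-sync trace
#' from the photoresistor, and session metadata (subject, group, day).
#'
#' @slot samples numeric matrix, channels x time, microvolts; rownames are the
#'   channel labels.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of unique 10-20 electrode names.
#' @slot sync numeric light-sync trace in `[0, 1]`, one value per sample.
#' @slot metadata list with at least `subject`, `group` ("active"/"sham") and
#'   `day`; free-form extras allowed.
#'
#' @seealso [simulateSession()], [readRecording()], [preprocessPipeline()]
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    sync = "numeric",
    metadata = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "number of sample rows must match number of channel labels")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@sync) > 0L && length(object@sync) != ncol(object@samples))
    msg <- c(msg, "'sync' must have one value per sample column")
  if (length(msg)) msg else TRUE
})

#' Session segment intervals
#'
#' Half-open, 0-based sample intervals `[start, end)` for the three light
#' conditions of a session, in protocol order: `no_light`, `constant_light`,
#' `stimulus`.
#'
#' @slot start integer vector of interval starts (0-based, inclusive), named
#'   by condition.
#' @slot end integer vector of interval ends (exclusive), named by condition.
#' @slot samplingRate sampling rate in Hz (for duration reporting).
#'
#' @seealso [detectSegments()]
#' @export
setClass("SessionSegments",
  representation(start = "numeric", end = "numeric", samplingRate = "numeric")
)

.SEGMENT_CONDITIONS <- c("no_light", "constant_light", "stimulus")

setValidity("SessionSegments", function(object) {
  msg <- character()
  if (!identical(names(object@start), .SEGMENT_CONDITIONS) ||
      !identical(names(object@end), .SEGMENT_CONDITIONS))
    msg <- c(msg, "intervals must be named no_light, constant_light, stimulus")
  else {
    if (any(object@end <= object@start))
      msg <- c(msg, "every segment must be nonempty")
    if (any(diff(object@start) <= 0) ||
        any(object@end[-3] > object@start[-1]))
      msg <- c(msg, "segments must be ordered and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Generative parameters for a synthetic EEG session. Defaults follow the
#' study protocol: 250 Hz sampling, 8 scalp channels, 5 min no light,
#' 5 min constant light, 20 min of 59.6 Hz square-wave stimulation at 50%
#' duty cycle.
#'
#' @slot samplingRate Hz.
#' @slot nChannels number of EEG channels.
#' @slot channelLabels 10-20 names, one per channel.
#' @slot segmentDurations seconds per condition, named `no_light`,
#'   `constant_light`, `stimulus`.
#' @slot stimulusFrequency flicker frequency, Hz.
#' @slot dutyCycle on-fraction of each flicker cycle, in (0, 1).
#' @slot entrainmentAmplitudes per-channel amplitude of the entrained 60 Hz
#'   component, microvolts (all zero = sham).
#' @slot phaseOffsets per-channel phase offset of the entrained component,
#'   radians.
#' @slot jitterKappa von Mises concentration of the per-channel phase-jitter
#'   process; `Inf` disables jitter, 0 gives uniform phase.
#' @slot jitterKnotS knot interval of the sample-and-hold jitter process,
#'   seconds.
#' @slot backgroundExponent spectral slope alpha of the 1/f^alpha background.
#' @slot backgroundSd total standard deviation of the colored background,
#'   microvolts.
#' @slot lineNoiseAmplitude amplitude of the 50 Hz line component, microvolts.
#' @slot whiteNoiseSd sensor white-noise SD, microvolts.
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [simulationConfig()], [simulateSession()]
#' @export
setClass("SimulationConfig",
  representation(
    samplingRate = "numeric",
    nChannels = "integer",
    channelLabels = "character",
    segmentDurations = "numeric",
    stimulusFrequency = "numeric",
    dutyCycle = "numeric",
    entrainmentAmplitudes = "numeric",
    phaseOffsets = "numeric",
    jitterKappa = "numeric",
    jitterKnotS = "numeric",
    backgroundExponent = "numeric",
    backgroundSd = "numeric",
    lineNoiseAmplitude = "numeric",
    whiteNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(object@channelLabels) != object@nChannels)
    msg <- c(msg, "one channel label per channel required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!identical(names(object@segmentDurations), .SEGMENT_CONDITIONS))
    msg <- c(msg, "segmentDurations must be named no_light, constant_light, stimulus")
  if (any(object@segmentDurations <= 0))
    msg <- c(msg, "all segment durations must be > 0")
  if (object@stimulusFrequency <= 0 ||
      object@stimulusFrequency >= object@samplingRate / 2)
    msg <- c(msg, "stimulusFrequency must lie in (0, samplingRate/2)")
  if (object@dutyCycle <= 0 || object@dutyCycle >= 1)
    msg <- c(msg, "dutyCycle must lie in (0, 1)")
  if (length(object@entrainmentAmplitudes) != object@nChannels ||
      any(object@entrainmentAmplitudes < 0))
    msg <- c(msg, "entrainmentAmplitudes must be >= 0, one per channel")
  if (length(object@phaseOffsets) != object@nChannels)
    msg <- c(msg, "phaseOffsets must have one entry per channel")
  if (object@jitterKappa < 0) msg <- c(msg, "jitterKappa must be >= 0")
  if (object@jitterKnotS <= 0) msg <- c(msg, "jitterKnotS must be > 0")
  if (object@backgroundSd < 0 || object@lineNoiseAmplitude < 0 ||
      object@whiteNoiseSd < 0)
    msg <- c(msg, "noise amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Closed-form expectations attached to a simulated session, used by recovery
#' tests: the expected fraction of 2-80 Hz power inside the analysis band
#' during the stimulus segment, and the expected phase-locking-value matrix
#' implied by independent von Mises phase jitter.
#'
#' @slot expectedBandFraction per-channel expected band fraction in `[0, 1]`.
#' @slot expectedPlv channels x channels matrix in `[0, 1]`, symmetric with
#'   unit diagonal; off-diagonals equal `(I1(kappa)/I0(kappa))^2`.
#' @slot seed integer seed echo.
#'
#' @export
setClass("SimTruth",
  representation(
    expectedBandFraction = "numeric",
    expectedPlv = "matrix",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  p <- object@expectedPlv
  if (nrow(p) != ncol(p)) msg <- c(msg, "expectedPlv must be square")
  else {
    if (max(abs(p - t(p))) > 1e-12) msg <- c(msg, "expectedPlv must be symmetric")
    if (any(abs(diag(p) - 1) > 1e-12)) msg <- c(msg, "expectedPlv diagonal must be 1")
    if (any(p < -1e-12 | p > 1 + 1e-12)) msg <- c(msg, "expectedPlv entries must lie in [0,1]")
  }
  if (any(object@expectedBandFraction < 0 | object@expectedBandFraction > 1))
    msg <- c(msg, "expectedBandFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Power spectral density estimate
#'
#' Averaged-periodogram (Welch) estimate on a regular frequency grid.
#'
#' @slot frequencies Hz grid, strictly increasing.
#' @slot power channels x frequencies matrix of spectral density, uV^2/Hz.
#' @slot resolution grid spacing, Hz.
#' @slot segmentLabel free-form label of the segment analysed.
#' @slot nWindows number of (unmasked) averaging windows used.
#'
#' @seealso [estimatePsd()], [bandFraction()]
#' @export
setClass("SpectralEstimate",
  representation(
    frequencies = "numeric",
    power = "matrix",
    resolution = "numeric",
    segmentLabel = "character",
    nWindows = "integer"
  )
)

setValidity("SpectralEstimate", function(object) {
  msg <- character()
  if (any(diff(object@frequencies) <= 0))
    msg <- c(msg, "frequency grid must be strictly increasing")
  if (ncol(object@power) != length(object@frequencies))
    msg <- c(msg, "power must have one column per frequency")
  if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
  if (object@resolution > 0.5 + 1e-9)
    msg <- c(msg, "resolution must be <= 0.5 Hz to resolve a 1 Hz band")
  if (length(msg)) msg else TRUE
})

#' Short-time Fourier transform result
#'
#' @slot times frame-center times, seconds.
#' @slot frequencies Hz grid of the window's natural resolution.
#' @slot power array frames x frequencies x channels, uV^2/Hz.
#' @slot windowS window length, seconds.
#' @slot hopS hop between frame starts, seconds.
#'
#' @seealso [computeStft()]
#' @export
setClass("StftResult",
  representation(
    times = "numeric",
    frequencies = "numeric",
    power = "array",
    windowS = "numeric",
    hopS = "numeric"
  )
)

setValidity("StftResult", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 3L) msg <- c(msg, "power must be a 3-d array")
  else {
    if (d[1] != length(object@times)) msg <- c(msg, "one frame per time")
    if (d[2] != length(object@frequencies)) msg <- c(msg, "one column per frequency")
  }
  if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Phase-locking value matrix
#'
#' Pairwise phase-locking values between channels at the stimulation band.
#' Raw matrices have entries in `[0, 1]`, are symmetric, and carry an exact
#' unit diagonal. Baseline-normalized matrices (`normalized = TRUE`) are
#' element-wise ratios to the no-light matrix: entries are positive and may
#' exceed 1; the diagonal is still 1.
#'
#' @slot values channels x channels numeric matrix with channel-label dimnames.
#' @slot condition light condition the matrix was computed from.
#' @slot day recording day.
#' @slot nSamples number of (unmasked, non-transient) samples used.
#' @slot normalized logical; `TRUE` for a baseline ratio matrix.
#'
#' @seealso [computePlv()], [normalizePlv()], [regionPairPlv()]
#' @export
setClass("PLVMatrix",
  representation(
    values = "matrix",
    condition = "character",
    day = "numeric",
    nSamples = "integer",
    normalized = "logical"
  )
)

setValidity("PLVMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "values must be symmetric")
    if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must equal 1")
    if (object@normalized) {
      if (any(v <= 0)) msg <- c(msg, "normalized entries must be positive")
    } else if (any(v < -1e-12 | v > 1 + 1e-9)) {
      msg <- c(msg, "raw PLV entries must lie in [0,1]")
    }
  }
  if (length(msg)) msg else TRUE
})
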