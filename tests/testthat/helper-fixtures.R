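# desk-scale simulation configs used across tests

smallConfig <- function(seed = 1, stimulusS = 60, baselineS = 12, ...) {
  simulationConfig(
    segmentDurations = c(no_light = baselineS, constant_light = baselineS,
                         stimulus = stimulusS),
    seed = seed, ...)
}

# a seeded tone matrix: channels x time, sin(2 pi f t + phase_c)
toneMatrix <- function(freq, fs = 250, durS = 10, phases = 0, amp = 1) {
  t <- (seq_len(round(durS * fs)) - 1) / fs
  m <- t(vapply(phases, function(p) amp * sin(2 * pi * freq * t + p),
                numeric(length(t))))
  m
}

# extract the raw (unpreprocessed) stimulus-segment samples of a session
rawStimulus <- function(session) {
  cfg <- recordingMetadata(session$recording)$segmentDurations
  fs <- samplingRate(session$recording)
  n <- ncol(eegSamples(session$recording))
  nStim <- round(cfg[["stimulus"]] * fs)
  eegSamples(session$recording)[, (n - nStim + 1):n, drop = FALSE]
}
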