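#' @include AllClasses.R utils.R
NULL

.DEFAULT_LABELS <- c("Fp1", "Fp2", "C3", "C4", "T5", "T6", "O1", "O2")

#' Build a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. Defaults reproduce the
#' study protocol: 250 Hz sampling, 8 channels, segments of 300/300/1200 s,
#' a 59.6 Hz flicker at 50% duty cycle, 2 uV entrained amplitude on every
#' channel, evenly spread channel phases, concentrated phase jitter
#' (kappa = 8) on 2 s sample-and-hold knots, a 1/f background of 10 uV total
#' SD, 5 uV of 50 Hz line noise and 1 uV sensor white noise. Set
#' `entrainmentAmplitudes = 0` for a sham session.
#'
#' @param samplingRate Hz.
#' @param nChannels number of EEG channels.
#' @param channelLabels 10-20 electrode names.
#' @param segmentDurations named seconds for `no_light`, `constant_light`,
#'   `stimulus` (scalable for desk-size runs).
#' @param stimulusFrequency flicker frequency, Hz; must be below Nyquist.
#' @param dutyCycle flicker on-fraction in (0, 1).
#' @param entrainmentAmplitudes per-channel 60 Hz component amplitude,
#'   microvolts; recycled to `nChannels`.
#' @param phaseOffsets per-channel phase, radians; default evenly spaced.
#' @param jitterKappa von Mises concentration of phase jitter (>= 0, may be
#'   `Inf` to disable jitter).
#' @param jitterKnotS jitter knot interval, seconds.
#' @param backgroundExponent 1/f^alpha slope of the colored background.
#' @param backgroundSd total SD of the colored background, microvolts.
#' @param lineNoiseAmplitude 50 Hz sinusoid amplitude, microvolts.
#' @param whiteNoiseSd white sensor noise SD, microvolts.
#' @param seed integer seed for all randomness.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(segmentDurations = c(no_light = 60,
#'   constant_light = 60, stimulus = 60))
#' cfg
#' @export
simulationConfig <- function(samplingRate = 250,
                             nChannels = 8,
                             channelLabels = .DEFAULT_LABELS,
                             segmentDurations = c(no_light = 300,
                                                  constant_light = 300,
                                                  stimulus = 1200),
                             stimulusFrequency = 59.6,
                             dutyCycle = 0.5,
                             entrainmentAmplitudes = 2,
                             phaseOffsets = NULL,
                             jitterKappa = 8,
                             jitterKnotS = 2,
                             backgroundExponent = 1,
                             backgroundSd = 10,
                             lineNoiseAmplitude = 5,
                             whiteNoiseSd = 1,
                             seed = 1L) {
  nChannels <- as.integer(nChannels)
  if (is.null(phaseOffsets))
    phaseOffsets <- 2 * pi * (seq_len(nChannels) - 1) / nChannels
  amps <- rep_len(entrainmentAmplitudes, nChannels)
  if (any(amps < 0))
    stop("entrainment amplitudes must be non-negative", call. = FALSE)
  new("SimulationConfig",
    samplingRate = samplingRate,
    nChannels = nChannels,
    channelLabels = channelLabels[seq_len(nChannels)],
    segmentDurations = segmentDurations,
    stimulusFrequency = stimulusFrequency,
    dutyCycle = dutyCycle,
    entrainmentAmplitudes = amps,
    phaseOffsets = rep_len(phaseOffsets, nChannels),
    jitterKappa = jitterKappa,
    jitterKnotS = jitterKnotS,
    backgroundExponent = backgroundExponent,
    backgroundSd = backgroundSd,
    lineNoiseAmplitude = lineNoiseAmplitude,
    whiteNoiseSd = whiteNoiseSd,
    seed = as.integer(seed))
}

#' Generate the light stimulus waveform
#'
#' Binary on/off square wave at the flicker frequency, sampled at the EEG
#' rate, plus the stimulus period in milliseconds truncated to three
#' decimals (59.6 Hz gives 16.778 ms).
#'
#' @param frequency flicker frequency, Hz; must lie in (0, samplingRate/2).
#' @param duty on-fraction of each cycle, in (0, 1).
#' @param duration seconds.
#' @param samplingRate Hz.
#' @return list with `trace` (numeric 0/1 vector) and `periodMs`.
#' @examples
#' w <- generateStimulusWaveform(59.6, 0.5, 1, 250)
#' w$periodMs
#' @export
generateStimulusWaveform <- function(frequency, duty, duration, samplingRate) {
  .assert(frequency > 0 && frequency < samplingRate / 2,
          sprintf("stimulus frequency must lie in (0, %g) Hz, below Nyquist; got %g",
                  samplingRate / 2, frequency))
  .assert(duty > 0 && duty < 1, "duty cycle must lie in (0, 1)")
  n <- round(duration * samplingRate)
  t <- (seq_len(n) - 1) / samplingRate
  trace <- as.numeric((frequency * t) %% 1 < duty)
  list(trace = trace, periodMs = trunc(1000 / frequency * 1000) / 1000)
}

# continuous one-sided background density (uV^2/Hz) implied by the config;
# colored 1/f^alpha component is band-limited to [0.5, Nyquist]
.backgroundDensity <- function(config, f) {
  alpha <- config@backgroundExponent
  fLow <- 0.5
  fHigh <- config@samplingRate / 2
  norm <- if (abs(alpha - 1) < 1e-12) log(fHigh / fLow) else
    (fHigh^(1 - alpha) - fLow^(1 - alpha)) / (1 - alpha)
  colored <- ifelse(f >= fLow & f <= fHigh,
                    config@backgroundSd^2 * f^(-alpha) / norm, 0)
  colored + config@whiteNoiseSd^2 / fHigh
}

#' Generate multichannel background noise
#'
#' Each channel is the sum of 1/f^alpha colored noise (band-limited to
#' 0.5 Hz-Nyquist, total SD `backgroundSd`), a 50 Hz line-noise sinusoid
#' with a per-channel random phase, and white sensor noise. Deterministic
#' given the config seed; a channel's draws are consumed in the order
#' colored spectrum, line phase, white noise, channel by channel.
#'
#' @param config a [SimulationConfig-class].
#' @param nSamples number of samples (> 0).
#' @return channels x samples numeric matrix, microvolts.
#' @export
generateBackground <- function(config, nSamples) {
  .assert(nSamples > 0, "nSamples must be > 0")
  validObject(config)
  fs <- config@samplingRate
  n <- as.integer(nSamples)
  nch <- config@nChannels
  set.seed(config@seed)
  # frequency-domain shaping gains, symmetric over FFT bins
  freqs <- (0:(n - 1)) / n * fs
  freqs <- pmin(freqs, fs - freqs)          # absolute frequency per bin
  alpha <- config@backgroundExponent
  s <- ifelse(freqs >= 0.5, freqs^(-alpha / 2), 0)
  sNorm <- sqrt(mean(s^2))
  t <- (seq_len(n) - 1) / fs
  out <- matrix(0, nch, n, dimnames = list(config@channelLabels, NULL))
  for (c in seq_len(nch)) {
    colored <- 0
    if (config@backgroundSd > 0 && sNorm > 0) {
      w <- stats::rnorm(n)
      colored <- Re(stats::fft(stats::fft(w) * s, inverse = TRUE)) / n
      colored <- colored * config@backgroundSd / sNorm
    } else {
      stats::rnorm(n)                        # keep draw order fixed
    }
    linePhase <- stats::runif(1, 0, 2 * pi)
    line <- config@lineNoiseAmplitude * sin(2 * pi * 50 * t + linePhase)
    white <- if (config@whiteNoiseSd > 0)
      stats::rnorm(n, 0, config@whiteNoiseSd) else { stats::rnorm(n); 0 }
    out[c, ] <- colored + line + white
  }
  out
}

# fraction of the jitter-broadened (sample-and-hold, knot interval T) tone
# energy that falls inside [band[1], band[2]] around carrier f0
.jitterInbandFraction <- function(f0, knotS, band) {
  dens <- function(f) {
    u <- knotS * (f - f0)
    ifelse(abs(u) < 1e-12, knotS, sin(pi * u)^2 / (pi * u)^2 * knotS)
  }
  stats::integrate(dens, band[1], band[2], rel.tol = 1e-8)$value
}

#' Expected analysis-band power fraction implied by a configuration
#'
#' Closed-form per-channel fraction of total (2-80 Hz, excluding 49-51 Hz)
#' power that lies in the analysis band during the stimulus segment. The
#' entrained tone contributes a coherent line at the carrier weighted
#' `R^2 = (I1(kappa)/I0(kappa))^2` plus an incoherent component broadened by
#' the sample-and-hold phase jitter, of which only the in-band part counts.
#'
#' @param config a [SimulationConfig-class].
#' @param band analysis band, Hz.
#' @param totalBand total-power band, Hz.
#' @param exclude notch-adjacent interval removed from the total, Hz.
#' @return numeric vector of per-channel expected fractions.
#' @export
expectedBandFraction <- function(config, band = c(59.5, 60.5),
                                 totalBand = c(2, 80), exclude = c(49, 51)) {
  f0 <- config@stimulusFrequency
  bgIn <- stats::integrate(function(f) .backgroundDensity(config, f),
                           band[1], band[2], rel.tol = 1e-8)$value
  bgTot <- stats::integrate(function(f) .backgroundDensity(config, f),
                            totalBand[1], exclude[1], rel.tol = 1e-8)$value +
    stats::integrate(function(f) .backgroundDensity(config, f),
                     exclude[2], totalBand[2], rel.tol = 1e-8)$value
  R <- .vmResultant(config@jitterKappa)
  carrierIn <- f0 >= band[1] && f0 <= band[2]
  fIn <- if (R < 1) .jitterInbandFraction(f0, config@jitterKnotS, band) else 0
  tone <- config@entrainmentAmplitudes^2 / 2
  toneIn <- tone * (R^2 * as.numeric(carrierIn) + (1 - R^2) * fIn)
  unname((toneIn + bgIn) / (tone + bgTot))
}

#' Generate the stimulus-locked entrained component
#'
#' Channel `c` carries
#' `A_c * sin(2*pi*f_stim*t + phi_c + psi_c(t))` where `psi_c` is a
#' sample-and-hold von Mises(0, kappa) jitter process on `jitterKnotS`-second
#' knots, independent across channels. Returns the component together with a
#' [SimTruth-class]: expected off-diagonal PLV `(I1(kappa)/I0(kappa))^2`
#' (1 when jitter is disabled, 0 for kappa = 0) and the closed-form expected
#' band fraction.
#'
#' @param config a [SimulationConfig-class].
#' @param nSamples number of stimulus-segment samples.
#' @return list with `component` (channels x samples matrix, microvolts) and
#'   `truth` (a [SimTruth-class]).
#' @export
generateEntrainedComponent <- function(config, nSamples) {
  validObject(config)
  .assert(all(config@entrainmentAmplitudes >= 0),
          "entrainment amplitudes must be non-negative")
  fs <- config@samplingRate
  n <- as.integer(nSamples)
  nch <- config@nChannels
  set.seed(config@seed + 1L)
  t <- (seq_len(n) - 1) / fs
  kappa <- config@jitterKappa
  nKnots <- ceiling(n / fs / config@jitterKnotS) + 1L
  comp <- matrix(0, nch, n, dimnames = list(config@channelLabels, NULL))
  knotIdx <- pmin(nKnots, 1L + floor(t / config@jitterKnotS))
  for (c in seq_len(nch)) {
    psi <- .rvonmises(nKnots, kappa)[knotIdx]
    comp[c, ] <- config@entrainmentAmplitudes[c] *
      sin(2 * pi * config@stimulusFrequency * t + config@phaseOffsets[c] + psi)
  }
  R2 <- .vmResultant(kappa)^2
  plv <- matrix(R2, nch, nch,
                dimnames = list(config@channelLabels, config@channelLabels))
  diag(plv) <- 1
  truth <- new("SimTruth",
    expectedBandFraction = expectedBandFraction(config),
    expectedPlv = plv,
    seed = config@seed)
  list(component = comp, truth = truth)
}

#' Simulate a full three-segment EEG session
#'
#' Concatenates the protocol segments (no light, constant light, stimulus).
#' The entrained component is present only during the stimulus segment and
#' only when any amplitude is positive (zero amplitudes = sham). The sync
#' channel is 0 during no light, high during constant light (with a 0.2 s
#' light-off switching gap at the very end of the constant segment, so that
#' both light-on onsets are detectable and coincide exactly with segment
#' starts) and carries the flicker waveform during stimulation.
#'
#' @param config a [SimulationConfig-class].
#' @param subject subject identifier stored in the metadata.
#' @param day recording day stored in the metadata.
#' @param group `"active"`, `"sham"`, or `NULL` to infer from the amplitudes.
#' @return list with `recording` (an [EEGRecording-class]) and `truth`
#'   (a [SimTruth-class]).
#' @examples
#' cfg <- simulationConfig(segmentDurations = c(no_light = 10,
#'   constant_light = 10, stimulus = 20), seed = 7)
#' sess <- simulateSession(cfg)
#' sess$recording
#' @export
simulateSession <- function(config, subject = "sim01", day = 1, group = NULL) {
  validObject(config)
  fs <- config@samplingRate
  nSeg <- as.integer(round(fs * config@segmentDurations))
  nTot <- sum(nSeg)
  bg <- generateBackground(config, nTot)
  ent <- generateEntrainedComponent(config, nSeg[3])
  samples <- bg
  stimStart <- nSeg[1] + nSeg[2]
  active <- any(config@entrainmentAmplitudes > 0)
  if (active)
    samples[, (stimStart + 1):nTot] <-
      samples[, (stimStart + 1):nTot] + ent$component
  gap <- round(0.2 * fs)
  syncConst <- rep(1, nSeg[2])
  if (nSeg[2] > gap) syncConst[(nSeg[2] - gap + 1):nSeg[2]] <- 0
  stimWave <- generateStimulusWaveform(config@stimulusFrequency,
                                       config@dutyCycle,
                                       nSeg[3] / fs, fs)$trace
  sync <- c(rep(0, nSeg[1]), syncConst, stimWave)
  rec <- new("EEGRecording",
    samples = samples,
    samplingRate = fs,
    channelLabels = config@channelLabels,
    sync = sync,
    metadata = list(
      subject = subject,
      group = group %||% if (active) "active" else "sham",
      day = day,
      seed = config@seed,
      segmentDurations = config@segmentDurations))
  list(recording = rec, truth = ent$truth)
}
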