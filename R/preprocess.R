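#' @include AllClasses.R utils.R
#' @importFrom signal butter filtfilt Arma
NULL

# apply a filter forward-backward to every row of a channels x time matrix
.filtfiltRows <- function(filt, x) {
  out <- x
  for (r in seq_len(nrow(x))) out[r, ] <- signal::filtfilt(filt, x[r, ])
  out
}

.recApply <- function(recording, fun) {
  recording@samples <- fun(recording@samples)
  recording
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (quality factor `q`, default 35) applied forward
#' and backward to every EEG channel; the sync trace is untouched. Removes
#' the 50 Hz line component while sparing the neighbourhood beyond about
#' +-3 Hz.
#'
#' @param recording an [EEGRecording-class] or a channels x time matrix.
#' @param center notch frequency, Hz (must be below Nyquist).
#' @param q notch quality factor (center / -3 dB width).
#' @param samplingRate Hz; required for matrix input, taken from the object
#'   otherwise.
#' @return same type as the input, filtered.
#' @export
setGeneric("notchFilter",
  function(recording, center = 50, q = 35, samplingRate = NULL)
    standardGeneric("notchFilter"))

.notchCoefs <- function(center, q, fs) {
  .assert(center > 0 && center < fs / 2,
          sprintf("notch center must lie in (0, %g) Hz", fs / 2))
  w0 <- 2 * pi * center / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' @rdname notchFilter
setMethod("notchFilter", "EEGRecording",
  function(recording, center, q, samplingRate) {
    filt <- .notchCoefs(center, q, recording@samplingRate)
    .recApply(recording, function(x) .filtfiltRows(filt, x))
  })

#' @rdname notchFilter
setMethod("notchFilter", "matrix",
  function(recording, center, q, samplingRate) {
    .assert(!is.null(samplingRate), "samplingRate required for matrix input")
    .filtfiltRows(.notchCoefs(center, q, samplingRate), recording)
  })

#' Zero-phase Butterworth band-pass filter
#'
#' Butterworth coefficients of the given order applied forward and backward
#' (zero phase distortion, effective order doubled). Default 0.5-80 Hz.
#'
#' @inheritParams notchFilter
#' @param low,high band edges, Hz; `0 < low < high < Nyquist`.
#' @param order Butterworth prototype order.
#' @return same type as the input, filtered.
#' @export
setGeneric("bandpassFilter",
  function(recording, low = 0.5, high = 80, order = 2, samplingRate = NULL)
    standardGeneric("bandpassFilter"))

.bandCoefs <- function(low, high, order, fs) {
  .assert(low > 0 && low < high && high < fs / 2,
          sprintf("band edges must satisfy 0 < low < high < %g Hz; got [%g, %g]",
                  fs / 2, low, high))
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  roots <- tryCatch(Mod(polyroot(rev(filt$a))), error = function(e) Inf)
  # poles this close to the unit circle ring for ~1e5 samples under
  # forward-backward filtering, which no session-length segment supports
  .assert(all(is.finite(roots)) && all(roots < 1 - 1e-5) &&
            all(is.finite(filt$b)),
          sprintf(paste0("band [%g, %g] Hz is too narrow for stable order-%d ",
                         "coefficients at %g Hz sampling; widen the band or ",
                         "reduce the order"), low, high, order, fs))
  filt
}

#' @rdname bandpassFilter
setMethod("bandpassFilter", "EEGRecording",
  function(recording, low, high, order, samplingRate) {
    filt <- .bandCoefs(low, high, order, recording@samplingRate)
    .recApply(recording, function(x) .filtfiltRows(filt, x))
  })

#' @rdname bandpassFilter
setMethod("bandpassFilter", "matrix",
  function(recording, low, high, order, samplingRate) {
    .assert(!is.null(samplingRate), "samplingRate required for matrix input")
    .filtfiltRows(.bandCoefs(low, high, order, samplingRate), recording)
  })

#' Common average reference
#'
#' Subtracts the across-channel mean from every sample so that the mean over
#' EEG channels is zero at each time point. The sync trace is untouched.
#'
#' @param recording an [EEGRecording-class] or a channels x time matrix.
#' @return same type as the input, re-referenced.
#' @export
setGeneric("averageReference",
  function(recording) standardGeneric("averageReference"))

.avgRef <- function(x) {
  .assert(nrow(x) >= 2, "average referencing requires at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' @rdname averageReference
setMethod("averageReference", "EEGRecording",
  function(recording) .recApply(recording, .avgRef))

#' @rdname averageReference
setMethod("averageReference", "matrix",
  function(recording) .avgRef(recording))

#' Detect the three light-condition segments from the sync trace
#'
#' A 100 ms moving-maximum envelope of the sync trace is thresholded at half
#' its dynamic range. Contiguous supra-threshold runs are light-on blocks:
#' the first is the constant-light condition, the second the flicker
#' stimulus; everything before the first onset is the no-light baseline.
#' Invariant to any positive rescaling of the sync trace.
#'
#' @param recording an [EEGRecording-class] with a sync trace.
#' @return a [SessionSegments-class] with half-open 0-based sample intervals.
#' @export
detectSegments <- function(recording) {
  sync <- recording@sync
  .assert(length(sync) > 0, "recording has no sync trace")
  fs <- recording@samplingRate
  win <- max(1L, round(0.1 * fs))
  # trailing moving maximum: bridges flicker off-phases without shifting
  # light-on onsets (a step edge is recovered exactly)
  n <- length(sync)
  env <- sync
  for (k in seq_len(win - 1L))
    env <- pmax(env, c(rep(sync[1], k), sync[seq_len(n - k)]))
  rng <- range(sync)
  thr <- rng[1] + 0.5 * diff(rng)
  on <- env > thr
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  if (length(blocks) < 2L)
    stop(sprintf(
      "segmentation needs two light-on blocks but found %d (block starts: %s)",
      length(blocks),
      if (length(blocks)) paste(starts[blocks] - 1L, collapse = ", ") else "none"),
      call. = FALSE)
  onset1 <- starts[blocks[1]] - 1L          # 0-based
  onset2 <- starts[blocks[2]] - 1L
  end2 <- ends[blocks[2]]
  new("SessionSegments",
    start = c(no_light = 0, constant_light = onset1, stimulus = onset2),
    end = c(no_light = onset1, constant_light = onset2, stimulus = end2),
    samplingRate = fs)
}

#' Mask artifact-contaminated windows
#'
#' Splits each segment into consecutive windows (default 1 s) and masks any
#' window in which any EEG channel exceeds the amplitude threshold. Masked
#' windows are excluded from every downstream power and synchrony estimate.
#' A segment whose mask covers more than half of it triggers a warning that
#' is also recorded on the returned object.
#'
#' @param recording an [EEGRecording-class].
#' @param segments a [SessionSegments-class].
#' @param threshold absolute amplitude threshold, microvolts.
#' @param windowS window length, seconds.
#' @return list with `mask` (logical per sample; TRUE = rejected),
#'   `intervals` (data frame: segment label, 0-based start, end), and
#'   `warnings` (character).
#' @export
rejectArtifacts <- function(recording, segments, threshold = 100, windowS = 1) {
  .assert(threshold > 0, "threshold must be > 0")
  fs <- recording@samplingRate
  x <- recording@samples
  n <- ncol(x)
  mask <- rep(FALSE, n)
  win <- max(1L, round(windowS * fs))
  intervals <- list()
  warnings <- character()
  bounds <- segmentBounds(segments)
  for (i in seq_len(nrow(bounds))) {
    s0 <- bounds$start[i]; s1 <- min(bounds$end[i], n)
    wStarts <- seq(s0, s1 - 1L, by = win)
    for (ws in wStarts) {
      we <- min(ws + win, s1)
      if (is.finite(threshold) &&
          any(abs(x[, (ws + 1):we, drop = FALSE]) > threshold)) {
        mask[(ws + 1):we] <- TRUE
        intervals[[length(intervals) + 1L]] <-
          data.frame(label = bounds$condition[i], start = ws, end = we)
      }
    }
    frac <- mean(mask[(s0 + 1):s1])
    if (frac > 0.5) {
      w <- sprintf("artifact mask covers %.0f%% of segment '%s'",
                   100 * frac, bounds$condition[i])
      warning(w, call. = FALSE)
      warnings <- c(warnings, w)
    }
  }
  list(mask = mask,
       intervals = if (length(intervals)) do.call(rbind, intervals)
                   else data.frame(label = character(), start = numeric(),
                                   end = numeric()),
       warnings = warnings)
}

#' Write an artifact mask as a BED-like interval list
#'
#' Plain-text three-column table (label, 0-based start sample, end sample).
#'
#' @param artifacts result of [rejectArtifacts()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMask <- function(artifacts, path) {
  utils::write.table(artifacts$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: 50 Hz notch, 0.5-80 Hz zero-phase Butterworth
#' band-pass, common average reference, sync-based segmentation, and
#' amplitude-threshold artifact masking. Filtering precedes segmentation, so
#' filter edge transients fall into the no-light head; downstream estimation
#' additionally trims 1 s from both ends of every segment.
#'
#' @param recording an [EEGRecording-class].
#' @param notchHz notch center, Hz.
#' @param band band-pass edges, Hz.
#' @param order Butterworth prototype order.
#' @param artifactThreshold amplitude threshold, microvolts.
#' @return list with `recording` (filtered, re-referenced), `segments`,
#'   `mask` (logical), `artifacts` (interval table) and `warnings`.
#' @export
preprocessPipeline <- function(recording, notchHz = 50, band = c(0.5, 80),
                               order = 2, artifactThreshold = 100) {
  rec <- notchFilter(recording, center = notchHz)
  rec <- bandpassFilter(rec, low = band[1], high = band[2], order = order)
  rec <- averageReference(rec)
  segments <- detectSegments(rec)
  art <- rejectArtifacts(rec, segments, threshold = artifactThreshold)
  list(recording = rec, segments = segments, mask = art$mask,
       artifacts = art$intervals, warnings = art$warnings)
}

#' Extract a trimmed, mask-aware segment
#'
#' Returns the sample matrix of one light condition with 1 s trimmed from
#' both ends (filter/segmentation transients) together with the aligned
#' artifact mask.
#'
#' @param recording an [EEGRecording-class].
#' @param segments a [SessionSegments-class].
#' @param condition `"no_light"`, `"constant_light"` or `"stimulus"`.
#' @param mask optional logical per-sample artifact mask for the whole
#'   recording.
#' @param trimS seconds trimmed from each end of the segment.
#' @return list with `samples` (channels x time), `mask` (logical) and
#'   `startSample` (0-based offset of the first returned sample).
#' @export
segmentSamples <- function(recording, segments, condition, mask = NULL,
                           trimS = 1) {
  .assert(condition %in% .SEGMENT_CONDITIONS,
          sprintf("unknown condition '%s'", condition))
  fs <- recording@samplingRate
  s0 <- segments@start[[condition]] + round(trimS * fs)
  s1 <- segments@end[[condition]] - round(trimS * fs)
  .assert(s1 > s0, sprintf("segment '%s' vanishes after trimming", condition))
  idx <- (s0 + 1):s1
  list(samples = recording@samples[, idx, drop = FALSE],
       mask = if (is.null(mask)) rep(FALSE, length(idx)) else mask[idx],
       startSample = s0)
}
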