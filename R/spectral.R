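#' @include AllClasses.R utils.R
NULL

#' Welch power spectral density estimate
#'
#' Averaged periodogram with Hamming-tapered windows (default 4 s, 50%
#' overlap, giving a 0.25 Hz grid at 250 Hz sampling). Windows containing
#' any masked (artifact) sample are skipped entirely. The estimate is scaled
#' as one-sided density, so its integral over frequency matches the
#' time-domain variance (taper-corrected).
#'
#' @param samples channels x time numeric matrix (a vector is treated as one
#'   channel), microvolts.
#' @param samplingRate Hz.
#' @param windowS window length, seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @param mask optional logical per-sample vector; TRUE = excluded.
#' @param segmentLabel label stored on the result.
#' @return a [SpectralEstimate-class].
#' @examples
#' fs <- 250; t <- seq(0, 20, by = 1 / fs)[-1]
#' psd <- estimatePsd(sin(2 * pi * 60 * t), fs)
#' psd
#' @export
estimatePsd <- function(samples, samplingRate, windowS = 4, overlap = 0.5,
                        mask = NULL, segmentLabel = "segment") {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  n <- ncol(samples)
  fs <- samplingRate
  minS <- 8
  if (n < minS * fs)
    stop(sprintf(
      "segment too short for PSD estimation: %.2f s available, %.0f s required",
      n / fs, minS), call. = FALSE)
  nw <- round(windowS * fs)
  hop <- max(1L, round(nw * (1 - overlap)))
  if (is.null(mask)) mask <- rep(FALSE, n)
  starts <- seq(1L, n - nw + 1L, by = hop)
  usable <- vapply(starts, function(s) !any(mask[s:(s + nw - 1L)]), TRUE)
  if (!any(usable))
    stop(sprintf(
      "no artifact-free %g s window available for PSD estimation (need >= %g s clean)",
      windowS, minS), call. = FALSE)
  starts <- starts[usable]
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- nw %/% 2 + 1L
  acc <- matrix(0, nrow(samples), nf)
  for (s in starts) {
    seg <- samples[, s:(s + nw - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)               # per-window demeaning
    X <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
    P <- Mod(X[seq_len(nf), , drop = FALSE])^2 * scale
    P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]  # one-sided
    acc <- acc + t(P)
  }
  acc <- acc / length(starts)
  freqs <- (seq_len(nf) - 1) * fs / nw
  rownames(acc) <- rownames(samples)
  new("SpectralEstimate",
    frequencies = freqs,
    power = acc,
    resolution = fs / nw,
    segmentLabel = segmentLabel,
    nWindows = length(starts))
}

#' Band power as a fraction of total power
#'
#' Discrete band power: spectral density summed over the grid points inside
#' the band (inclusive of both edges) times the grid spacing, divided by
#' the same sum over the total band with the notch-adjacent interval
#' excluded from the denominator. The rectangle rule keeps the full weight
#' of peaks that fall on an edge grid point, so a tone's leakage mass is
#' conserved between numerator and denominator.
#'
#' @param psd a [SpectralEstimate-class].
#' @param band analysis band, Hz (default 59.5-60.5, containing the 59.6 Hz
#'   stimulus fundamental).
#' @param totalBand total-power range, Hz.
#' @param exclude interval removed from the denominator (emptied by the
#'   notch), Hz.
#' @return named numeric vector of per-channel fractions in `[0, 1]`.
#' @export
bandFraction <- function(psd, band = c(59.5, 60.5), totalBand = c(2, 80),
                         exclude = c(49, 51)) {
  .assert(band[1] >= totalBand[1] && band[2] <= totalBand[2],
          "analysis band must lie within the total band")
  f <- psd@frequencies
  integ <- function(lo, hi) {
    sel <- f >= lo - 1e-9 & f <= hi + 1e-9
    rowSums(psd@power[, sel, drop = FALSE]) * psd@resolution
  }
  num <- integ(band[1], band[2])
  den <- integ(totalBand[1], exclude[1]) + integ(exclude[2], totalBand[2])
  if (any(den <= 0))
    stop("zero total power in the 2-80 Hz range; degenerate segment",
         call. = FALSE)
  pmin(pmax(num / den, 0), 1)
}

#' Normalize a band fraction to the no-light baseline
#'
#' @param stimulusFraction band fraction(s) from a light condition.
#' @param baselineFraction band fraction(s) from the no-light condition.
#' @return element-wise ratio (dimensionless).
#' @export
normalizeToBaseline <- function(stimulusFraction, baselineFraction) {
  if (any(baselineFraction <= 0))
    stop("baseline band fraction must be > 0 (degenerate no-light segment)",
         call. = FALSE)
  stimulusFraction / baselineFraction
}

#' Short-time Fourier transform
#'
#' Hamming-windowed STFT (default 0.5 s window, 0.25 s hop). The frame count
#' equals `floor((n - window) / hop) + 1`; frame starts are rounded down to
#' whole samples when the hop is fractional.
#'
#' @param samples channels x time matrix (vector = one channel).
#' @param samplingRate Hz.
#' @param windowS window length, seconds.
#' @param hopS hop between frame starts, seconds.
#' @return an [StftResult-class].
#' @export
computeStft <- function(samples, samplingRate, windowS = 0.5, hopS = 0.25) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  fs <- samplingRate
  n <- ncol(samples)
  nw <- round(windowS * fs)
  hop <- hopS * fs
  if (n < nw)
    stop(sprintf("segment (%d samples) shorter than one %g s window (%d samples)",
                 n, windowS, nw), call. = FALSE)
  nFrames <- floor((n - nw) / hop) + 1
  starts <- floor((seq_len(nFrames) - 1) * hop)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- nw %/% 2 + 1L
  nch <- nrow(samples)
  pow <- array(0, dim = c(nFrames, nf, nch))
  for (m in seq_len(nFrames)) {
    seg <- samples[, (starts[m] + 1):(starts[m] + nw), drop = FALSE]
    X <- stats::mvfft(t(seg * rep(w, each = nch)))
    P <- Mod(X[seq_len(nf), , drop = FALSE])^2 * scale
    P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]
    pow[m, , ] <- P
  }
  new("StftResult",
    times = (starts + nw / 2) / fs,
    frequencies = (seq_len(nf) - 1) * fs / nw,
    power = pow,
    windowS = windowS,
    hopS = hopS)
}

#' Baseline-normalized band power in consecutive time bins
#'
#' Splits the stimulus segment into consecutive bins (default 4 minutes; a
#' trailing partial bin is dropped), estimates the band fraction per bin and
#' channel, and normalizes by the no-light baseline fraction.
#'
#' @param samples channels x time matrix of the stimulus segment.
#' @param samplingRate Hz.
#' @param baselineFraction per-channel no-light band fraction (names must
#'   cover the sample rownames).
#' @param binS bin length, seconds (>= 8 s so a PSD can be formed).
#' @param mask optional logical per-sample artifact mask for the segment.
#' @param band,totalBand,exclude passed to [bandFraction()].
#' @return data frame with columns `bin`, `binStartS`, `channel`,
#'   `rawFraction`, `normalized`.
#' @export
timeBinnedPower <- function(samples, samplingRate, baselineFraction,
                            binS = 240, mask = NULL,
                            band = c(59.5, 60.5), totalBand = c(2, 80),
                            exclude = c(49, 51)) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  n <- ncol(samples)
  binN <- round(binS * samplingRate)
  nBins <- floor(n / binN)
  if (nBins < 1)
    stop(sprintf("stimulus segment (%.1f s) holds no full %g s bin",
                 n / samplingRate, binS), call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, n)
  out <- vector("list", nBins)
  for (b in seq_len(nBins)) {
    idx <- ((b - 1) * binN + 1):(b * binN)
    psd <- estimatePsd(samples[, idx, drop = FALSE], samplingRate,
                       windowS = min(4, binS / 2), mask = mask[idx],
                       segmentLabel = sprintf("bin%d", b))
    raw <- bandFraction(psd, band, totalBand, exclude)
    ch <- rownames(samples) %||% as.character(seq_len(nrow(samples)))
    base <- if (is.null(names(baselineFraction))) baselineFraction
            else baselineFraction[ch]
    out[[b]] <- data.frame(
      bin = b,
      binStartS = (b - 1) * binS,
      channel = ch,
      rawFraction = unname(raw),
      normalized = unname(normalizeToBaseline(raw, base)))
  }
  do.call(rbind, out)
}

#' Default anatomical region map
#'
#' @return named list of channel sets: Frontal (Fp1, Fp2), Central (C3, C4),
#'   Temporal (T5, T6), Occipital (O1, O2).
#' @export
defaultRegionMap <- function() {
  list(Frontal = c("Fp1", "Fp2"), Central = c("C3", "C4"),
       Temporal = c("T5", "T6"), Occipital = c("O1", "O2"))
}

#' Aggregate per-channel values into anatomical regions
#'
#' Arithmetic mean over each region's channels. Channels in the map but
#' absent from `values` are reported in the `missing` column; a region with
#' no present channel is an error.
#'
#' @param values named numeric vector (names = channel labels).
#' @param regionMap named list of channel sets, as [defaultRegionMap()].
#' @return data frame with `region`, `value`, `nChannels`, `missing`.
#' @export
aggregateByRegion <- function(values, regionMap = defaultRegionMap()) {
  .assert(!is.null(names(values)), "'values' must be named by channel")
  all <- unlist(regionMap)
  .assert(!anyDuplicated(all), "region channel sets must be disjoint")
  out <- lapply(names(regionMap), function(rg) {
    chans <- regionMap[[rg]]
    present <- intersect(chans, names(values))
    if (!length(present))
      stop(sprintf("region '%s' has no channel present in the data", rg),
           call. = FALSE)
    data.frame(region = rg,
               value = mean(values[present]),
               nChannels = length(present),
               missing = paste(setdiff(chans, present), collapse = ","))
  })
  do.call(rbind, out)
}
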