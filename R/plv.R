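#' @include AllClasses.R utils.R preprocess.R
NULL

#' Zero-phase narrowband filter around the stimulation frequency
#'
#' Second-order Butterworth band-pass (default 59.5-60.5 Hz) applied forward
#' and backward. The first and last second of the output are flagged as
#' filter transients via the `"transient"` attribute (a logical vector) and
#' are excluded from downstream phase statistics.
#'
#' @param samples channels x time matrix (vector = one channel).
#' @param samplingRate Hz.
#' @param band band edges, Hz; must lie within (0, Nyquist) and be wide
#'   enough for numerically stable coefficients.
#' @param order Butterworth prototype order.
#' @return filtered matrix with attribute `transient`.
#' @export
narrowbandFilter <- function(samples, samplingRate, band = c(59.5, 60.5),
                             order = 2) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  filt <- .bandCoefs(band[1], band[2], order, samplingRate)
  out <- .filtfiltRows(filt, samples)
  n <- ncol(out)
  tr <- rep(FALSE, n)
  edge <- min(round(samplingRate), floor(n / 2))
  if (edge > 0) tr[c(seq_len(edge), (n - edge + 1):n)] <- TRUE
  attr(out, "transient") <- tr
  out
}

#' Instantaneous phase via the Hilbert transform
#'
#' Phase of the analytic signal of each (narrowband) channel, wrapped to
#' (-pi, pi]. Any `"transient"` attribute on the input is propagated.
#'
#' @param samples narrowband channels x time matrix (vector = one channel).
#' @return matrix of per-sample phase, radians.
#' @export
instantaneousPhase <- function(samples) {
  tr <- attr(samples, "transient")
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  ph <- samples
  for (r in seq_len(nrow(samples))) ph[r, ] <- Arg(.analytic(samples[r, ]))
  attr(ph, "transient") <- tr
  ph
}

#' Phase-locking value matrix
#'
#' For channels i, j: `PLV_ij = |mean_n exp(1i * (phi_i(n) - phi_j(n)))|`
#' over all unmasked, non-transient samples. The diagonal is exactly 1; the
#' matrix is symmetric with entries in `[0, 1]`.
#'
#' @param phases channels x time matrix of instantaneous phase (radians),
#'   e.g. from [instantaneousPhase()]; a `"transient"` attribute is honored.
#' @param mask optional logical per-sample artifact mask (TRUE = dropped).
#' @param condition,day labels stored on the result.
#' @param minSamples minimum number of retained samples.
#' @return a [PLVMatrix-class].
#' @export
computePlv <- function(phases, mask = NULL, condition = "stimulus", day = NA_real_,
                       minSamples = 250) {
  .assert(nrow(phases) >= 2, "PLV needs at least 2 channels")
  n <- ncol(phases)
  keep <- rep(TRUE, n)
  tr <- attr(phases, "transient")
  if (!is.null(tr)) keep <- keep & !tr
  if (!is.null(mask)) keep <- keep & !mask
  nUsed <- sum(keep)
  if (nUsed < minSamples)
    stop(sprintf("PLV requires at least %d unmasked samples, only %d available",
                 minSamples, nUsed), call. = FALSE)
  ph <- phases[, keep, drop = FALSE]
  z <- exp(1i * ph)
  nch <- nrow(phases)
  v <- matrix(NA_real_, nch, nch)
  for (i in seq_len(nch)) {
    # the self-difference is identically zero, so v[i,i] evaluates to 1 exactly
    v[i, i] <- Mod(mean(exp(1i * (ph[i, ] - ph[i, ]))))
    if (i < nch) for (j in (i + 1):nch)
      v[i, j] <- v[j, i] <- Mod(mean(z[i, ] * Conj(z[j, ])))
  }
  labels <- rownames(phases) %||% as.character(seq_len(nch))
  dimnames(v) <- list(labels, labels)
  new("PLVMatrix", values = v, condition = condition, day = as.numeric(day),
      nSamples = as.integer(nUsed), normalized = FALSE)
}

#' Normalize a PLV matrix to the no-light baseline
#'
#' Element-wise ratio of a condition's PLV matrix to the no-light matrix.
#' The diagonal is exactly 1 by construction.
#'
#' @param plv a raw [PLVMatrix-class].
#' @param baseline the no-light [PLVMatrix-class].
#' @return a [PLVMatrix-class] with `normalized = TRUE`.
#' @export
normalizePlv <- function(plv, baseline) {
  .assert(!plv@normalized && !baseline@normalized,
          "normalizePlv expects raw PLV matrices")
  b <- baseline@values
  if (any(b <= 0)) {
    bad <- which(b <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("baseline PLV is zero for channel pair (%s, %s)",
                 rownames(b)[bad[1]], colnames(b)[bad[2]]), call. = FALSE)
  }
  v <- plv@values / b
  diag(v) <- 1
  new("PLVMatrix", values = v, condition = plv@condition, day = plv@day,
      nSamples = plv@nSamples, normalized = TRUE)
}

#' Mean PLV over all inter-regional channel pairs
#'
#' For every unordered pair of distinct regions, the mean of the PLV entries
#' over all cross-region channel pairs.
#'
#' @param plv a [PLVMatrix-class] (raw or normalized).
#' @param regionMap named list of channel sets, as [defaultRegionMap()].
#' @return data frame with `regionA`, `regionB`, `condition`, `day`,
#'   `value`, `nPairs`.
#' @export
regionPairPlv <- function(plv, regionMap = defaultRegionMap()) {
  v <- plv@values
  labels <- rownames(v)
  regions <- names(regionMap)
  out <- list()
  for (a in seq_len(length(regions) - 1)) {
    for (b in (a + 1):length(regions)) {
      chA <- intersect(regionMap[[regions[a]]], labels)
      chB <- intersect(regionMap[[regions[b]]], labels)
      if (!length(chA) || !length(chB))
        stop(sprintf("region pairing %s-%s has no channel pair present",
                     regions[a], regions[b]), call. = FALSE)
      vals <- v[chA, chB, drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        regionA = regions[a], regionB = regions[b],
        condition = plv@condition, day = plv@day,
        value = mean(vals), nPairs = length(vals))
    }
  }
  do.call(rbind, out)
}
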