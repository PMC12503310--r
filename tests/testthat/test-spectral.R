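fs <- 250

test_that("Welch PSD satisfies Parseval and locates tones", {
  x <- toneMatrix(60, durS = 20)
  psd <- estimatePsd(x, fs)
  expect_equal(psd@resolution, 0.25)
  expect_equal(psd@frequencies[which.max(psd@power[1, ])], 60)
  total <- sum(psd@power[1, ]) * psd@resolution
  expect_lt(abs(total - 0.5), 0.025)         # sinusoid power 1/2 within 5%
  # seeded white noise: flat spectrum
  set.seed(42)
  w <- matrix(rnorm(fs * 60), 1)
  pw <- estimatePsd(w, fs)
  sel <- pw@frequencies >= 2 & pw@frequencies <= 80
  fit <- stats::lm(log(pw@power[1, sel]) ~ pw@frequencies[sel])
  expect_lt(abs(unname(stats::coef(fit)[2])), 0.05)
  totalW <- sum(pw@power[1, ]) * pw@resolution
  expect_lt(abs(totalW - 1), 0.05)
  expect_equal(max(estimatePsd(matrix(0, 1, 5000), fs)@power), 0)
})

test_that("band fraction isolates in-band tones", {
  p60 <- estimatePsd(toneMatrix(60, durS = 20), fs)
  expect_gte(unname(bandFraction(p60)), 0.99)
  p10 <- estimatePsd(toneMatrix(10, durS = 20), fs)
  expect_lte(unname(bandFraction(p10)), 0.01)
  both <- toneMatrix(10, durS = 20) + toneMatrix(60, durS = 20)
  expect_equal(unname(bandFraction(estimatePsd(both, fs))), 0.5,
               tolerance = 0.04)
  expect_error(bandFraction(estimatePsd(matrix(0, 1, 5000), fs)),
               "zero total power")
  expect_error(bandFraction(p60, band = c(0.5, 60)), "within the total")
})

test_that("band fraction is scale invariant and amplitude monotone", {
  sess <- simulateSession(smallConfig(seed = 12, stimulusS = 30, baselineS = 10))
  stim <- rawStimulus(sess)
  f1 <- bandFraction(estimatePsd(stim, fs))
  f2 <- bandFraction(estimatePsd(stim * 13.7, fs))
  expect_equal(f1, f2, tolerance = 1e-12)
  base <- eegSamples(sess$recording)[, 1:(10 * fs)]
  expect_equal(normalizeToBaseline(f2, bandFraction(estimatePsd(base, fs))),
               normalizeToBaseline(f1, bandFraction(estimatePsd(base, fs))),
               tolerance = 1e-12)
  # amplitude ladder: strictly increasing stimulus-band fraction
  ladder <- sapply(c(0.5, 1, 2, 4, 8), function(a) {
    s <- simulateSession(smallConfig(seed = 12, stimulusS = 30, baselineS = 10,
                                     entrainmentAmplitudes = a))
    mean(bandFraction(estimatePsd(rawStimulus(s), fs)))
  })
  expect_true(all(diff(ladder) > 0))
})

test_that("Welch band fraction agrees with a full-segment DFT oracle", {
  # oracle: literal DFT of the whole segment, rectangle-rule band power
  dftFraction <- function(x, fs, band = c(59.5, 60.5), total = c(2, 80),
                          excl = c(49, 51)) {
    n <- length(x)
    P <- Mod(stats::fft(x))^2 / n^2
    f <- (0:(n - 1)) * fs / n
    half <- f <= fs / 2
    P <- 2 * P[half]; f <- f[half]
    inb <- function(lo, hi) sum(P[f >= lo - 1e-9 & f <= hi + 1e-9])
    inb(band[1], band[2]) / (inb(total[1], excl[1]) + inb(excl[2], total[2]))
  }
  sess <- simulateSession(smallConfig(seed = 30, stimulusS = 60, baselineS = 10,
                                      entrainmentAmplitudes = 3))
  stim <- rawStimulus(sess)
  for (ch in c(1, 5)) {
    welch <- unname(bandFraction(estimatePsd(stim[ch, , drop = FALSE], fs)))
    oracle <- dftFraction(stim[ch, ], fs)
    expect_lt(abs(welch - oracle) / oracle, 0.10)
  }
})

test_that("baseline normalization is a guarded ratio", {
  expect_equal(normalizeToBaseline(0.2, 0.2), 1)
  expect_equal(normalizeToBaseline(0.4, 0.2), 2)
  expect_error(normalizeToBaseline(0.4, 0), "baseline")
})

test_that("STFT frame geometry and stationarity behave as specified", {
  x <- toneMatrix(60, durS = 10)
  st <- computeStft(x, fs)
  expect_identical(dim(st@power)[1], 39L)     # floor((2500-125)/62.5)+1
  i60 <- which(st@frequencies == 60)
  p60 <- st@power[, i60, 1]
  expect_lt(stats::sd(p60) / mean(p60), 0.05)
  expect_equal(max(computeStft(matrix(0, 1, 2500), fs)@power), 0)
  expect_error(computeStft(matrix(0, 1, 100), fs), "shorter than one")
})

test_that("time-binned power follows the floor rule and stays stable", {
  # 20-minute stimulus at 4-minute bins: 5 bins
  x20 <- toneMatrix(60, durS = 1200, amp = 2) +
    matrix(rnorm(1200 * fs, sd = 3), 1)
  tb <- timeBinnedPower(x20, fs, baselineFraction = 0.01)
  expect_equal(max(tb$bin), 5)
  # stationary signal: per-bin spread below 20%
  expect_lt(diff(range(tb$normalized)) / mean(tb$normalized), 0.2)
  # 9-minute stimulus: partial third bin dropped
  tb9 <- timeBinnedPower(x20[, 1:(540 * fs), drop = FALSE], fs,
                         baselineFraction = 0.01)
  expect_equal(max(tb9$bin), 2)
  expect_error(timeBinnedPower(x20[, 1:(100 * fs), drop = FALSE], fs,
                               baselineFraction = 0.01), "no full")
})

test_that("regional aggregation averages the mapped channels", {
  vals <- c(Fp1 = 2, Fp2 = 4, C3 = 1, C4 = 1, T5 = 3, T6 = 3, O1 = 7, O2 = 9)
  agg <- aggregateByRegion(vals)
  expect_equal(agg$value[agg$region == "Frontal"], 3)
  expect_equal(agg$value[agg$region == "Occipital"], 8)
  flat <- aggregateByRegion(setNames(rep(5, 8), names(vals)))
  expect_true(all(flat$value == 5))
  expect_error(aggregateByRegion(vals[1:4]), "no channel present")
  # occipital-weighted simulation: occipital region dominates
  amps <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 6, 6)
  sess <- simulateSession(smallConfig(seed = 17, stimulusS = 30, baselineS = 10,
                                      entrainmentAmplitudes = amps))
  fr <- bandFraction(estimatePsd(rawStimulus(sess), fs))
  aggSim <- aggregateByRegion(fr)
  expect_identical(aggSim$region[which.max(aggSim$value)], "Occipital")
})
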