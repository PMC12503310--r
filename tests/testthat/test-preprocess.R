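fs <- 250

test_that("notch filter removes 50 Hz and spares the passband", {
  x50 <- toneMatrix(50, durS = 10)
  y50 <- notchFilter(x50, samplingRate = fs)
  mid <- 500:2000
  expect_lt(sqrt(mean(y50[, mid]^2)), 0.1 * sqrt(mean(x50[, mid]^2)))
  x10 <- toneMatrix(10, durS = 10)
  y10 <- notchFilter(x10, samplingRate = fs)
  expect_lt(abs(sqrt(mean(y10[, mid]^2)) / sqrt(mean(x10[, mid]^2)) - 1), 0.05)
  expect_equal(notchFilter(matrix(0, 2, 1000), samplingRate = fs),
               matrix(0, 2, 1000))
  expect_error(notchFilter(x50, center = 200, samplingRate = fs), "notch center")
})

test_that("band-pass is zero-phase, flat mid-band, and removes DC", {
  mid <- 500:2000
  # deep in-band tones pass essentially unattenuated
  for (f in c(10, 30)) {
    y <- bandpassFilter(toneMatrix(f, durS = 10), samplingRate = fs)
    expect_lt(abs(max(abs(y[, mid])) - 1), 0.05)
  }
  # 60 Hz sits on the shoulder of the order-2 upper edge: mild, condition-
  # independent attenuation that cancels in the baseline normalization
  y60 <- bandpassFilter(toneMatrix(60, durS = 10), samplingRate = fs)
  expect_gt(max(abs(y60[, mid])), 0.85)
  dc <- matrix(1, 1, 2500)
  expect_lt(max(abs(bandpassFilter(dc, samplingRate = fs)[, 500:2000])), 0.01)
  # zero-phase: a symmetric pulse stays symmetric about its center
  pulse <- matrix(0, 1, 2001)
  pulse[1, 950:1052] <- exp(-((-51:51)^2) / 200)
  yp <- bandpassFilter(pulse, samplingRate = fs)
  expect_lt(max(abs(yp[1, 1:1000] - yp[1, 2001:1002])), 1e-3)
  # cross-correlation peak lag of a 10 Hz sinusoid is zero
  x10 <- toneMatrix(10, durS = 10)
  y10 <- bandpassFilter(x10, samplingRate = fs)
  cc <- stats::ccf(drop(y10)[mid], drop(x10)[mid], lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpassFilter(matrix(0, 1, 100), low = 100, high = 80,
                             samplingRate = fs),
               "band edges")
})

test_that("average reference zeroes the cross-channel mean and needs 2+ channels", {
  set.seed(1)
  x <- matrix(rnorm(8000), 8, 1000)
  y <- averageReference(x)
  expect_lt(max(abs(colMeans(y))), 1e-9)
  v <- rbind(sin(1:100), -sin(1:100))
  expect_equal(averageReference(v), v)
  same <- rbind(sin(1:100), sin(1:100))
  expect_equal(max(abs(averageReference(same))), 0)
  expect_error(averageReference(matrix(1, 1, 100)), "2 channels")
  # sync untouched on recordings
  sess <- simulateSession(smallConfig(seed = 1, stimulusS = 4, baselineS = 2))
  expect_identical(syncTrace(averageReference(sess$recording)),
                   syncTrace(sess$recording))
})

test_that("segmentation recovers the constructed boundaries from the sync trace", {
  cfg <- smallConfig(seed = 4, stimulusS = 20, baselineS = 10)
  sess <- simulateSession(cfg)
  seg <- detectSegments(sess$recording)
  b <- segmentBounds(seg)
  expect_identical(b$condition, c("no_light", "constant_light", "stimulus"))
  # constant-light onset is a step edge: exact
  expect_identical(b$start[2], 2500)
  # flicker onset within one envelope window of construction
  expect_lt(abs(b$start[3] - 5000), 25)
  expect_true(all(b$end > b$start))
  # invariant to sync amplitude scaling
  scaled <- sess$recording
  scaled@sync <- scaled@sync * 7.3
  expect_identical(segmentBounds(detectSegments(scaled)), b)
  # all-zero sync fails with a block listing
  dark <- sess$recording
  dark@sync <- rep(0, length(dark@sync))
  expect_error(detectSegments(dark), "light-on blocks")
})

test_that("artifact rejection masks exactly the contaminated windows", {
  cfg <- smallConfig(seed = 6, stimulusS = 20, baselineS = 10)
  sess <- simulateSession(cfg)
  pp0 <- preprocessPipeline(sess$recording)
  expect_identical(sum(pp0$mask), 0L)
  # inject a 500 uV, 0.5 s spike into the stimulus segment
  rec <- sess$recording
  spikeIdx <- 6001:6125
  rec@samples[3, spikeIdx] <- rec@samples[3, spikeIdx] + 500
  art <- rejectArtifacts(rec, detectSegments(rec), threshold = 100)
  masked <- which(art$mask)
  # the spike spans samples 6001..6125; stimulus windows are 1 s from its
  # start, so exactly the overlapping windows are masked
  expect_true(all(spikeIdx %in% masked))
  expect_lt(length(masked), 3 * 250)
  expect_identical(sum(rejectArtifacts(rec, detectSegments(rec),
                                       threshold = Inf)$mask), 0L)
  expect_error(rejectArtifacts(rec, detectSegments(rec), threshold = -1),
               "threshold")
})

test_that("masked windows do not contribute to downstream power estimates", {
  cfg <- smallConfig(seed = 13, stimulusS = 30, baselineS = 10)
  sess <- simulateSession(cfg)
  pp <- preprocessPipeline(sess$recording)
  # corrupt two seconds of one channel with a huge in-band artifact
  rec <- sess$recording
  idx <- 8001:8500
  rec@samples[2, idx] <- rec@samples[2, idx] + 5000 * sin(2 * pi * 7 * idx / fs)
  pp2 <- preprocessPipeline(rec)
  expect_gt(sum(pp2$mask), 0)
  seg2 <- segmentSamples(pp2$recording, pp2$segments, "stimulus", mask = pp2$mask)
  f2 <- bandFraction(estimatePsd(seg2$samples, fs, mask = seg2$mask))
  # the clean recording, estimated over the very same unmasked windows,
  # gives the same band power: the artifact contributes nothing
  ref <- segmentSamples(pp$recording, pp$segments, "stimulus", mask = pp2$mask)
  fRef <- bandFraction(estimatePsd(ref$samples, fs, mask = ref$mask))
  expect_equal(unname(f2), unname(fRef), tolerance = 0.05)
})

test_that("the pipeline applies the documented order and keeps the 60 Hz component", {
  cfg <- smallConfig(seed = 10, stimulusS = 30, baselineS = 10,
                     entrainmentAmplitudes = 5)
  sess <- simulateSession(cfg)
  pp <- preprocessPipeline(sess$recording)
  b <- segmentBounds(pp$segments)
  expect_equal(b$duration_s, c(10, 10, 30), tolerance = 0.02)
  # repeated filtering alters the signal (idempotence is not claimed)
  twice <- bandpassFilter(pp$recording)
  expect_false(isTRUE(all.equal(eegSamples(twice), eegSamples(pp$recording))))
  # the chain retains the entrained band fraction
  rawStim <- rawStimulus(sess)
  fRaw <- bandFraction(estimatePsd(rawStim, fs))
  seg <- segmentSamples(pp$recording, pp$segments, "stimulus", mask = pp$mask)
  fChain <- bandFraction(estimatePsd(seg$samples, fs, mask = seg$mask))
  expect_true(all(fChain > 0.8 * fRaw))
})

test_that("segments that vanish after masking are rejected with the length", {
  x <- matrix(rnorm(250 * 6), 2, 750)
  expect_error(estimatePsd(x, fs), "8 s|required")
})
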