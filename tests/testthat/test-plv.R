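fs <- 250

test_that("narrowband filter passes 60 Hz, rejects 55 Hz, flags transients", {
  x60 <- toneMatrix(60, durS = 10)
  y <- narrowbandFilter(x60, fs)
  tr <- attr(y, "transient")
  expect_equal(sum(tr), 2 * fs)
  keep <- which(!tr)
  expect_lt(abs(max(abs(y[, keep])) - 1), 0.05)
  x55 <- toneMatrix(55, durS = 10)
  y55 <- narrowbandFilter(x55, fs)
  expect_lte(max(abs(y55[, keep])), 0.1)
  expect_equal(max(abs(narrowbandFilter(matrix(0, 1, 2500), fs))), 0)
})

test_that("instantaneous phase tracks a 60 Hz tone and relative shifts", {
  t <- (0:4999) / fs
  x <- sin(2 * pi * 60 * t)
  ph <- instantaneousPhase(matrix(x, 1))
  mid <- 500:4500
  up <- cumsum(c(ph[1, mid][1],
    ((diff(ph[1, mid]) + pi) %% (2 * pi)) - pi))
  slope <- unname(stats::coef(stats::lm(up ~ t[mid]))[2])
  expect_lt(abs(slope - 2 * pi * 60) / (2 * pi * 60), 0.001)
  # identical signals: zero phase difference everywhere
  two <- rbind(x, x)
  p2 <- instantaneousPhase(two)
  expect_equal(max(abs(p2[1, ] - p2[2, ])), 0)
  # quarter-period shift: constant pi/2 difference
  shifted <- rbind(sin(2 * pi * 60 * t), sin(2 * pi * 60 * t + pi / 2))
  ps <- instantaneousPhase(shifted)
  d <- (ps[2, mid] - ps[1, mid] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(d - pi / 2)), 0.01)
})

test_that("PLV matches its definition, with an exact unit diagonal", {
  t <- (0:4999) / fs
  sig <- rbind(sin(2 * pi * 60 * t), sin(2 * pi * 60 * t + pi / 4))
  ph <- instantaneousPhase(narrowbandFilter(sig, fs))
  plv <- computePlv(ph)
  expect_identical(unname(diag(plvValues(plv))), c(1, 1))
  expect_gt(plvValues(plv)[1, 2], 0.999)      # constant offset: PLV 1
  # independent uniform phases: PLV near the sqrt(pi)/(2 sqrt(N)) floor
  set.seed(7)
  rph <- matrix(stats::runif(3 * 10000, -pi, pi), 3)
  prand <- computePlv(rph)
  expect_lt(max(plvValues(prand)[upper.tri(plvValues(prand))]), 0.05)
  # oracle: naive two-pass loop over samples
  naive <- function(a, b) {
    s <- 0
    for (n in seq_along(a)) s <- s + exp(1i * (a[n] - b[n]))
    Mod(s / length(a))
  }
  for (pair in list(c(1, 2), c(2, 3)))
    expect_equal(plvValues(prand)[pair[1], pair[2]],
                 naive(rph[pair[1], ], rph[pair[2], ]), tolerance = 1e-12)
  expect_error(computePlv(rph[, 1:100]), "at least 250")
  expect_error(computePlv(rph[1, , drop = FALSE]), "2 channels")
})

test_that("PLV is invariant to common rotations and duplication-consistent", {
  set.seed(9)
  ph <- matrix(stats::runif(4 * 2000, -pi, pi), 4)
  p0 <- plvValues(computePlv(ph))
  rot <- ((ph + 1.234 + pi) %% (2 * pi)) - pi
  expect_equal(plvValues(computePlv(rot)), p0, tolerance = 1e-12)
  dup <- cbind(ph, ph)
  expect_equal(plvValues(computePlv(dup)), p0, tolerance = 1e-12)
  # masking the duplicate half reproduces the single-half matrix exactly
  mask <- c(rep(FALSE, 2000), rep(TRUE, 2000))
  expect_equal(plvValues(computePlv(dup, mask = mask)), p0, tolerance = 1e-15)
})

test_that("PLV recovers the von Mises closed form at high SNR", {
  kappa <- 8
  truthVal <- (besselI(kappa, 1) / besselI(kappa, 0))^2
  pooled <- list()
  for (s in 1:4) {
    cfg <- smallConfig(seed = 400 + s, stimulusS = 60, baselineS = 8,
                       entrainmentAmplitudes = 20, jitterKappa = kappa)
    stim <- rawStimulus(simulateSession(cfg))
    ph <- instantaneousPhase(narrowbandFilter(stim, fs))
    pooled[[s]] <- ph[, !attr(ph, "transient")]
  }
  plv <- plvValues(computePlv(do.call(cbind, pooled)))
  emp <- mean(plv[upper.tri(plv)])
  expect_lt(abs(emp - truthVal), 0.05)
})

test_that("PLV normalization is an element-wise guarded ratio", {
  m <- matrix(0.4, 3, 3); diag(m) <- 1
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  mk <- function(v, cond) new("PLVMatrix", values = v, condition = cond,
                              day = 1, nSamples = 1000L, normalized = FALSE)
  same <- normalizePlv(mk(m, "stimulus"), mk(m, "no_light"))
  expect_true(all(plvValues(same) == 1))
  twice <- m; twice[upper.tri(twice)] <- 0.8; twice[lower.tri(twice)] <- 0.8
  norm <- normalizePlv(mk(twice, "stimulus"), mk(m, "no_light"))
  expect_true(all(plvValues(norm)[upper.tri(twice)] == 2))
  zero <- m; zero[1, 2] <- zero[2, 1] <- 0
  expect_error(normalizePlv(mk(m, "stimulus"), mk(zero, "no_light")),
               "channel pair \\([AB], [AB]\\)")
})

test_that("region-pair PLV averages cross-region pairs", {
  labels <- c("Fp1", "Fp2", "C3", "C4", "T5", "T6", "O1", "O2")
  v <- matrix(0.3, 8, 8, dimnames = list(labels, labels)); diag(v) <- 1
  plv <- new("PLVMatrix", values = v, condition = "stimulus", day = 1,
             nSamples = 1000L, normalized = FALSE)
  rp <- regionPairPlv(plv)
  expect_true(all(rp$value == 0.3))
  expect_true(all(rp$nPairs == 4))
  expect_identical(nrow(rp), 6L)
  # frontal-occipital coupling only: that pair is maximal
  set.seed(3)
  base <- stats::runif(2000, -pi, pi)
  ph <- rbind(base, base + 0.2, matrix(stats::runif(4 * 2000, -pi, pi), 4),
              base + 0.4, base + 0.9)
  rownames(ph) <- labels
  rpSim <- regionPairPlv(computePlv(ph))
  top <- rpSim[which.max(rpSim$value), ]
  expect_setequal(c(top$regionA, top$regionB), c("Frontal", "Occipital"))
})

test_that("over-narrow bands are rejected with guidance", {
  x <- toneMatrix(60, durS = 5)
  expect_error(narrowbandFilter(x, fs, band = c(60 - 5e-4, 60 + 5e-4)),
               "too narrow|stable")
})
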