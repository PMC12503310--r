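test_that("Shapiro-Wilk wrapper gates normality as expected", {
  sw <- shapiroWilk(c(-1, 0, 1))
  expect_equal(sw$statistic, 1, tolerance = 1e-9)
  set.seed(31)
  expect_lt(shapiroWilk(stats::rexp(50))$p.value, 0.01)
  expect_error(shapiroWilk(c(1, 2)), "3 <= n")
  # null p values are uniform
  set.seed(32)
  ps <- replicate(500, shapiroWilk(stats::rnorm(25))$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rank-sum test takes the exact path and matches enumeration", {
  t1 <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(t1$exact)
  expect_equal(t1$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(5, 6, 7), c(5, 6, 7))$p.value, 1)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "nonempty")
  set.seed(41)
  for (rep in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1); y <- sample(200:300, n2)  # no ties
    got <- wilcoxonRankSum(x, y)
    expect_true(got$exact)
    expect_equal(got$p.value, ranksumOracle(x, y), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H and exact p match hand computation and enumeration", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_identical(kruskalWallis(list(rep(2, 3), rep(2, 4)))$p.value, 1)
  set.seed(51)
  for (sizes in list(c(3, 3), c(2, 3, 3), c(3, 2, 2))) {
    vals <- sample(50, sum(sizes))
    groups <- split(vals, rep(seq_along(sizes), sizes))
    got <- kruskalWallis(groups)
    expect_true(got$exact)
    expect_equal(got$p.value, kwOracle(groups), tolerance = 1e-10)
  }
  # with ties
  tied <- list(c(1, 2, 2), c(2, 3, 4), c(5, 5))
  expect_equal(kruskalWallis(tied)$p.value, kwOracle(tied), tolerance = 1e-10)
  # large-sample path agrees with the chi-square cross-check (kruskal.test)
  set.seed(52)
  big <- list(stats::rnorm(15), stats::rnorm(15, 0.5), stats::rnorm(15, 1))
  got <- kruskalWallis(big)
  expect_false(got$exact)
  ref <- stats::kruskal.test(big)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  # two groups: chi-square path equals the z^2 of the tie-corrected
  # rank-sum normal approximation (no continuity correction)
  two <- list(c(3, 9, 1, 14, 8, 12, 6), c(2, 15, 4, 11, 13, 5, 7, 10))
  gotTwo <- kruskalWallis(two, exactLimit = 0)
  n1 <- 7; n2 <- 8; N <- 15
  U <- sum(rank(unlist(two))[1:7]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(gotTwo$p.value, stats::pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Dunn post hoc reproduces the rank-mean z formula with Bonferroni", {
  eq <- dunnPosthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(eq$z, 0)
  expect_equal(eq$p.adjusted, 1)
  dn <- dunnPosthoc(list(d1 = c(1, 2, 3), d2 = c(4, 5, 6), d3 = c(7, 8, 9)))
  # rank means 2, 5, 8; se = sqrt((9*10/12)*(2/3)) = sqrt(5)
  expect_equal(dn$z[dn$groupA == "d1" & dn$groupB == "d2"], -3 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(dn$z[dn$groupA == "d1" & dn$groupB == "d3"], -6 / sqrt(5),
               tolerance = 1e-12)
  expect_gt(abs(dn$z[3]), 0)
  expect_equal(dn$p.adjusted, pmin(1, 3 * dn$p.raw), tolerance = 1e-15)
  expect_true(all(dn$p.adjusted >= dn$p.raw))
  sub <- dunnPosthoc(list(d1 = c(1, 2, 3), d2 = c(4, 5, 6), d3 = c(7, 8, 9)),
                     pairs = cbind("d1", "d3"))
  expect_equal(sub$p.adjusted, sub$p.raw, tolerance = 1e-15)
})

test_that("Fisher exact matches hypergeometric enumeration for all small margins", {
  f <- fisherExact2x2(matrix(c(3, 0, 0, 3), 2))
  expect_equal(f$p.value, 0.1, tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(4, 4, 2, 2), 2))$p.value, 1)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, cc, b, d), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExact2x2(tab)$p.value, fisherOracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("two-way ANOVA matches the hand-computed balanced decomposition", {
  v <- c(1, 2, 3, 4, 5, 6, 9, 10)
  g <- rep(c("a", "b"), each = 4)
  tm <- rep(rep(c("x", "y"), each = 2), 2)
  res <- twoWayAnova(v, g, tm)
  expect_equal(res$ss, c(50, 18, 2), tolerance = 1e-10)
  expect_equal(res$F, c(100, 36, 4), tolerance = 1e-10)
  expect_equal(res$p[3], 0.1161165, tolerance = 1e-6)
  flat <- twoWayAnova(rep(3, 8), g, tm)
  expect_equal(flat$F, c(0, 0, 0))
  expect_equal(flat$p, c(1, 1, 1))
  expect_error(twoWayAnova(v[-(1:2)], g[-(1:2)], tm[-(1:2)]), "empty design cell")
  # additive model, no interaction: interaction p is uniform under the null
  set.seed(61)
  ps <- replicate(200, {
    gg <- rep(c("a", "b"), each = 12)
    tt <- rep(rep(c("x", "y", "z"), each = 4), 2)
    vv <- stats::rnorm(24) + (gg == "b") * 1 + (tt == "y") * 0.5
    twoWayAnova(vv, gg, tt)$p[3]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the decision flow gates on Shapiro-Wilk normality", {
  set.seed(71)
  normalCells <- list(a = stats::rnorm(40), b = stats::rnorm(40, 1))
  expect_identical(decisionFlow(normalCells)$branch, "parametric")
  skewCells <- list(a = stats::rexp(40), b = stats::rexp(40))
  flow <- decisionFlow(skewCells)
  expect_identical(flow$branch, "nonparametric")
  expect_identical(flow$recommendedTest, "Wilcoxon rank-sum")
  three <- list(a = stats::rexp(40), b = stats::rexp(40), c = stats::rexp(40))
  expect_match(decisionFlow(three)$recommendedTest, "Kruskal")
  # reproducible given the seed
  set.seed(72); f1 <- decisionFlow(list(a = stats::rnorm(20), b = stats::rnorm(20)))
  set.seed(72); f2 <- decisionFlow(list(a = stats::rnorm(20), b = stats::rnorm(20)))
  expect_identical(f1, f2)
})
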