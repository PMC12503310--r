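#' @include utils.R
#' @importFrom car Anova
#' @importFrom stats shapiro.test wilcox.test kruskal.test fisher.test
#'   pchisq pnorm lm var aov
NULL

.testResult <- function(method, statistic, p, groupSizes, tails = "two-sided",
                        tieCorrected = FALSE, extra = list()) {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  structure(
    c(list(method = method, statistic = statistic, p.value = min(p, 1),
           groupSizes = groupSizes, tails = tails,
           tieCorrected = tieCorrected), extra),
    class = "entrainTest")
}

#' @export
print.entrainTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s; n = %s)\n",
              x$method, x$statistic, x$p.value, x$tails,
              paste(x$groupSizes, collapse = "/")))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the package's
#' common test-result structure. Used as the gate of [decisionFlow()].
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return an `entrainTest` list: method, statistic (W), p.value, groupSizes.
#' @export
shapiroWilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (n = %d)", length(x)),
         call. = FALSE)
  ht <- stats::shapiro.test(x)
  .testResult("Shapiro-Wilk", unname(ht$statistic), ht$p.value, length(x))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided by default. The exact null distribution is used when the pooled
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (each nonempty).
#' @param tails `"two-sided"`, `"less"` or `"greater"`.
#' @return an `entrainTest` with the rank-sum statistic W (number of
#'   x-before-y wins) and extra field `exact`.
#' @export
wilcoxonRankSum <- function(x, y, tails = c("two.sided", "less", "greater")) {
  tails <- match.arg(tails)
  .assert(length(x) >= 1 && length(y) >= 1, "both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = tails,
                                            exact = exact, correct = TRUE))
  .testResult("Wilcoxon rank-sum", unname(ht$statistic), ht$p.value,
              c(length(x), length(y)),
              tails = if (tails == "two.sided") "two-sided" else tails,
              tieCorrected = ties, extra = list(exact = exact))
}

# tie-corrected Kruskal-Wallis H from a pooled sample and group labels
.kwH <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  sums <- tapply(r, g, sum)
  ns <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H <- H / corr
  H
}

# exhaustive permutation distribution of H for small pooled samples:
# enumerate all distinct assignments of the pooled ranks to the groups
.kwExactP <- function(values, sizes, Hobs) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(1)
  hOf <- function(rankSumsSq) {
    (12 / (N * (N + 1)) * sum(rankSumsSq / sizes) - 3 * (N + 1)) / corr
  }
  ge <- 0; tot <- 0
  recurse <- function(idx, gi, acc) {
    if (gi == length(sizes)) {
      H <- hOf(c(acc, sum(r[idx])^2))
      tot <<- tot + 1
      if (H >= Hobs - 1e-12) ge <<- ge + 1
      return(invisible())
    }
    combs <- utils::combn(idx, sizes[gi])
    for (k in seq_len(ncol(combs)))
      recurse(setdiff(idx, combs[, k]), gi + 1L,
              c(acc, sum(r[combs[, k]])^2))
  }
  recurse(seq_len(N), 1L, numeric(0))
  ge / tot
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic. For pooled sample sizes up to `exactLimit`
#' (default 12) the p value comes from exhaustive enumeration of the
#' permutation distribution of H; beyond that, from the chi-square
#' approximation with k-1 degrees of freedom. When every observation is
#' identical, H = 0 and p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, total N >= 3).
#' @param exactLimit largest pooled N for which the exact path is taken.
#' @return an `entrainTest` with extra fields `df` and `exact`.
#' @export
kruskalWallis <- function(groups, exactLimit = 12) {
  .assert(is.list(groups) && length(groups) >= 2,
          "at least two groups required")
  ns <- lengths(groups)
  .assert(all(ns >= 1) && sum(ns) >= 3, "each group nonempty, total N >= 3")
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), ns)
  k <- length(groups)
  if (var(values) == 0)
    return(.testResult("Kruskal-Wallis", 0, 1, ns, tieCorrected = TRUE,
                       extra = list(df = k - 1, exact = FALSE)))
  H <- .kwH(values, g)
  exact <- sum(ns) <= exactLimit
  p <- if (exact) .kwExactP(values, ns, H)
       else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  .testResult("Kruskal-Wallis", H, p, ns, tieCorrected = TRUE,
              extra = list(df = k - 1, exact = exact))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' For groups i, j within a Kruskal-Wallis family:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p values
#' are Bonferroni-adjusted by the number of compared pairs.
#'
#' @param groups named list of numeric samples (k >= 2; post hoc normally
#'   follows a k >= 3 family).
#' @param pairs optional 2-column matrix/data frame of group-name pairs to
#'   compare; default all unordered pairs.
#' @return data frame of class `dunnPosthoc`: `groupA`, `groupB`, `z`,
#'   `p.raw`, `p.adjusted`, `familySize`.
#' @export
dunnPosthoc <- function(groups, pairs = NULL) {
  .assert(is.list(groups) && length(groups) >= 2,
          "at least two groups required")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), ns)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(groups), 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  m <- nrow(pairs)
  .assert(m >= 1, "comparison family must contain at least one pair")
  out <- data.frame(groupA = pairs[, 1], groupB = pairs[, 2],
                    z = NA_real_, p.raw = NA_real_, p.adjusted = NA_real_,
                    familySize = m)
  for (i in seq_len(m)) {
    a <- match(pairs[i, 1], names(groups))
    b <- match(pairs[i, 2], names(groups))
    .assert(!is.na(a) && !is.na(b),
            sprintf("unknown group in pair (%s, %s)", pairs[i, 1], pairs[i, 2]))
    se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / ns[a] + 1 / ns[b]))
    z <- if (se > 0) (rbar[a] - rbar[b]) / se else 0
    out$z[i] <- z
    out$p.raw[i] <- 2 * stats::pnorm(-abs(z))
  }
  out$p.adjusted <- pmin(1, m * out$p.raw)
  class(out) <- c("dunnPosthoc", "data.frame")
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value: the sum of hypergeometric probabilities, with margins
#' fixed, of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return an `entrainTest` with the odds-ratio estimate as statistic.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  .assert(all(dim(table) == c(2, 2)), "a 2x2 table is required")
  .assert(all(table >= 0) && all(abs(table - round(table)) < 1e-9),
          "counts must be nonnegative integers")
  ht <- stats::fisher.test(round(table))
  .testResult("Fisher exact", unname(ht$estimate), ht$p.value,
              rowSums(table))
}

#' Two-way analysis of variance (group x time)
#'
#' Type-II sums of squares via [car::Anova()] on a cells-means linear model
#' with interaction; for balanced data this coincides with the classical
#' decomposition. A zero-variance response is reported as the no-effect
#' path: all sums of squares 0, F = 0, p = 1.
#'
#' @param values numeric response.
#' @param group factor-like, first factor (e.g. active/sham).
#' @param time factor-like, second factor (e.g. day).
#' @return data frame with `term`, `ss`, `df`, `F`, `p`.
#' @export
twoWayAnova <- function(values, group, time) {
  group <- factor(group)
  time <- factor(time)
  .assert(nlevels(group) >= 2 && nlevels(time) >= 2,
          "both factors need at least two levels")
  cells <- table(group, time)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: group '%s' x time '%s'",
                 levels(group)[bad[1]], levels(time)[bad[2]]), call. = FALSE)
  }
  terms <- c("group", "time", "group:time")
  if (stats::var(values) == 0)
    return(data.frame(term = terms, ss = 0, df = NA_real_, F = 0, p = 1))
  fit <- stats::lm(values ~ group * time)
  a <- car::Anova(fit, type = 2)
  idx <- match(terms, rownames(a))
  data.frame(term = terms,
             ss = a[["Sum Sq"]][idx],
             df = a[["Df"]][idx],
             F = a[["F value"]][idx],
             p = a[["Pr(>F)"]][idx])
}

#' Normality-gated test selection
#'
#' Applies the Shapiro-Wilk test to every cell; if any cell deviates from
#' normality at `alpha`, the nonparametric branch is selected (rank-sum for
#' two cells, Kruskal-Wallis plus Dunn post hoc otherwise), else the
#' parametric branch.
#'
#' @param cells named list of numeric samples (one per group/condition cell).
#' @param alpha normality-gate significance level.
#' @return list with `branch` ("parametric"/"nonparametric"),
#'   `recommendedTest`, `shapiro` (data frame of per-cell W and p) and
#'   `alpha`.
#' @export
decisionFlow <- function(cells, alpha = 0.05) {
  .assert(is.list(cells) && length(cells) >= 2,
          "at least two cells required")
  if (is.null(names(cells))) names(cells) <- paste0("cell", seq_along(cells))
  sw <- lapply(cells, shapiroWilk)
  tab <- data.frame(cell = names(cells),
                    W = vapply(sw, function(s) s$statistic, 0),
                    p = vapply(sw, function(s) s$p.value, 0))
  nonparam <- any(tab$p < alpha)
  branch <- if (nonparam) "nonparametric" else "parametric"
  recommended <- if (length(cells) == 2) {
    if (nonparam) "Wilcoxon rank-sum" else "two-sample t"
  } else {
    if (nonparam) "Kruskal-Wallis + Dunn-Bonferroni" else "ANOVA"
  }
  list(branch = branch, recommendedTest = recommended, shapiro = tab,
       alpha = alpha)
}
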