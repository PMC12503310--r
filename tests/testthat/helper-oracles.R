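# independent enumeration oracles used throughout this file

# rank-sum: exact two-sided p by enumerating all assignments of ranks
ranksumOracle <- function(x, y) {
  m <- length(x); N <- m + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(N, m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= uObs + 1e-9), mean(us >= uObs - 1e-9)))
}

# Kruskal-Wallis: exact p over all distinct group assignments, with the
# tie-corrected H statistic delegated to stats::kruskal.test
kwOracle <- function(groups) {
  v <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(v)
  hOf <- function(g) unname(stats::kruskal.test(v, factor(g))$statistic)
  Hobs <- hOf(rep(seq_along(groups), sizes))
  hs <- c()
  enumerate <- function(idx, gi, labels) {
    if (gi == length(sizes)) {
      labels[idx] <- gi
      hs <<- c(hs, hOf(labels))
      return(invisible())
    }
    combs <- utils::combn(idx, sizes[gi])
    for (k in seq_len(ncol(combs))) {
      l2 <- labels
      l2[combs[, k]] <- gi
      enumerate(setdiff(idx, combs[, k]), gi + 1L, l2)
    }
  }
  enumerate(seq_len(N), 1L, rep(NA_integer_, N))
  mean(hs >= Hobs - 1e-12)
}

# Fisher: two-sided p from the hypergeometric distribution directly
fisherOracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(ks, r1, r2, c1)
  pObs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}
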