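# Independent oracles used to cross-check the package's test statistics.

# Exact two-sided Wilcoxon rank-sum p by enumeration of all C(N, n_a)
# assignments of the pooled ranks (tie-free samples only).
wilcoxEnumP <- function(a, b) {
  na <- length(a)
  N <- na + length(b)
  r <- rank(c(a, b))
  mu <- na * (N - na) / 2
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  stats <- apply(utils::combn(N, na), 2, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(stats - mu) >= abs(W - mu) - 1e-9)
}

# Brute-force Fisher exact p for a 2 x 3 table: direct double loop over the
# two free cells (independent of the package's recursive enumeration).
fisherBruteP <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  lp <- function(t) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(sum(t) + 1) - sum(lgamma(t + 1))
  obs <- lp(tab)
  tot <- 0
  for (a in 0:min(rs[1], cs[1])) {
    for (b in 0:min(rs[1] - a, cs[2])) {
      c3 <- rs[1] - a - b
      t <- rbind(c(a, b, c3), c(cs[1] - a, cs[2] - b, cs[3] - c3))
      if (any(t < 0)) next
      l <- lp(t)
      if (l <= obs + log1p(1e-7)) tot <- tot + exp(l)
    }
  }
  min(1, tot)
}

# Random 2 x 3 contingency table with all margins positive.
randomTable23 <- function(maxTotal = 60) {
  repeat {
    n <- sample(6:maxTotal, 1)
    tab <- matrix(tabulate(sample(1:6, n, replace = TRUE), 6), 2, 3)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
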