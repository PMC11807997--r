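# Independent brute-force oracles used to check the package's statistics.

# exact two-sided rank-sum p by enumerating every split of the combined
# values into a case group of the observed size (no ties assumed)
wilcoxEnumOracle <- function(case, ref) {
  vals <- c(case, ref)
  n <- length(vals); n1 <- length(case)
  r <- rank(vals)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  w <- apply(splits, 2L, function(ix)
    sum(rank(vals)[ix]) - n1 * (n1 + 1) / 2)
  pLo <- mean(w <= wObs); pHi <- mean(w >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# upper-tail hypergeometric p by enumerating all C(N, n) draws
hyperEnumOracle <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  inPath <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% inPath))
  mean(overlaps >= x)
}

# AUC by counting concordant case-control pairs (ties get half credit)
aucPairOracle <- function(scores, labels, caseLabel) {
  cs <- scores[labels == caseLabel]
  ct <- scores[labels != caseLabel]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}
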