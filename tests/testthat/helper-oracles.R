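# Brute-force enumeration oracles for the exact Wilcoxon tests, independent
# of the package's subset-sum-counting implementation.

bruteRankSum <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y), ties.method = "average")
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  combos <- utils::combn(N, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
}

bruteSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(V - mu) - 1e-9)
}
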