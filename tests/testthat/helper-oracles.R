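# Independent oracles used by both the module tests and the acceptance
# suite. Deliberately naive implementations: plain loops, no shared code
# with the package internals they check.

# plug-in mutual information by explicit cell loops (bits)
oracle_mi <- function(a, b) {
  n <- length(a)
  total <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        total <- total + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  total
}

# brute-force greedy MID ordering: re-scores every candidate from scratch
oracle_mrmr <- function(D, y) {
  p <- ncol(D)
  rel <- vapply(seq_len(p), function(j) oracle_mi(D[, j], y), 0)
  order_out <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      if (length(order_out) == 0) return(rel[f])
      red <- mean(vapply(order_out, function(s) oracle_mi(D[, f], D[, s]), 0))
      rel[f] - red
    }, 0)
    pick <- remaining[which(crit >= max(crit) - 1e-12)[1]]
    order_out <- c(order_out, pick)
    remaining <- setdiff(remaining, pick)
  }
  order_out
}

# exhaustive hypergeometric upper tail: enumerate every size-n draw from an
# N-gene universe whose first M genes are annotated
enum_upper_tail <- function(N, M, n, m) {
  if (n == 0) return(if (m == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}
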