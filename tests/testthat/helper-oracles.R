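# Independent brute-force oracles. These deliberately avoid the code paths
# (and even the base helpers) used by the implementation.

# Average ranks computed from first principles.
oracle_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

# Spearman rho as Pearson on hand-computed ranks, explicit sum formula.
oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Textbook BH step-up: q_i = min over j with p_(j) >= p_i of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- which(ps >= p[i])
    q[i] <- min(pmin(ps[cand] * m / cand, 1))
  }
  q
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (tables as or less probable than
# the observed one, with the customary relative tolerance for float ties).
oracle_fisher_p <- function(a, b, c, d) {
  row1 <- a + b
  col1 <- a + c
  n <- a + b + c + d
  ks <- max(0, col1 - (c + d)):min(row1, col1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(col1, k) + lchoose(n - col1, row1 - k) - lchoose(n, row1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Probe-bias weighted mean by 1-bp nearest-probe integration.
oracle_voronoi_mean <- function(rel_pos, beta, span = 5000) {
  grid <- seq(-span, span, by = 0.5)
  nearest <- vapply(grid, function(x) which.min(abs(rel_pos - x)), integer(1))
  mean(beta[nearest])
}
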