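# Independent brute-force oracles for the exact tests. These enumerate the
# null distributions directly and are deliberately separate from the
# package's computation paths.

# Mann-Whitney U for a given assignment of the combined sample.
u_statistic <- function(ranks_x, m) {
  sum(ranks_x) - m * (m + 1) / 2
}

# Exact two-sided Mann-Whitney p by enumerating all C(m+n, m) group
# assignments of the combined values (doubled smaller tail, capped at 1).
mw_enumeration_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- u_statistic(r[seq_len(m)], m)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(i) u_statistic(r[i], m))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^m sign
# assignments over the mid-ranked absolute differences.
wsr_enumeration_oracle <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Ordinary equal-variance two-sample t on one antibody row.
ordinary_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), nx + ny - 2))
}

# Random tie-free sample drawn by jittering a permutation (no duplicates).
rand_tiefree <- function(n) {
  sample(seq_len(100), n) + stats::runif(n, -0.2, 0.2)
}
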