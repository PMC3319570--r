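# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: correlation from the raw product-moment sums,
# p-values straight from the t tail, BH by literal definition.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * (1 - pt(abs(t), n - 2)), n = n)
}

# P(edge classified strong | independent Gaussian genes, n samples):
# the effective threshold is the larger of r_min and the r at which the
# two-sided t-based p equals alpha; tail probability from the t transform.
oracle_null_strong_rate <- function(n, r_min = 0.75, alpha = 0.05) {
  df <- n - 2
  t_alpha <- qt(1 - alpha / 2, df)
  r_alpha <- t_alpha / sqrt(t_alpha^2 + df)
  r_eff <- max(r_min, r_alpha)
  t_eff <- r_eff * sqrt(df / (1 - r_eff^2))
  2 * pt(t_eff, df, lower.tail = FALSE)
}

# literal BH definition: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# small helper: gene x sample matrix of independent N(0,1) rows
random_matrix <- function(genes, samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), genes, samples)
  dimnames(m) <- list(sprintf("g%02d", seq_len(genes)),
                      sprintf("s%02d", seq_len(samples)))
  m
}
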