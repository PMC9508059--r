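# Independent brute-force oracles, deliberately written from first
# principles (sums of squares, rank arithmetic, pair enumeration) so they
# share no code path with the package implementations they check.

# One-way within-subject ANOVA from explicit sums of squares.
# m: subjects x conditions matrix of cell means.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2, mse = ss_err / df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Friedman chi-squared from within-subject rank sums (no-ties formula).
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  list(chi2 = chi2, df = k - 1,
       p = pchisq(chi2, k - 1, lower.tail = FALSE))
}

# Mann-Whitney U by exhaustive pair enumeration (ties count 1/2).
oracle_mann_whitney_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Wilcoxon signed-rank V and normal-approximation z (zeros dropped).
oracle_signed_rank <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  nz <- length(d)
  mu <- nz * (nz + 1) / 4
  ties <- table(r)
  sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(ties^3 - ties) / 48
  list(V = v, z = (v - mu) / sqrt(sig2))
}
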