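# Independent oracles and small fixture builders used across tests.

# Plain-arithmetic Pearson chi-square, written out longhand so it shares
# no code with the package's vectorised fitters.
oracle_chi2 <- function(counts, probs) {
  N <- sum(counts)
  total <- 0
  for (k in seq_along(counts)) {
    e <- max(probs[k], 1e-9)
    total <- total + (counts[k] - N * e)^2 / (N * e)
  }
  total
}

# Brute-force 1PBM scan at a fine step, independent of the package grid.
oracle_best_binomial <- function(counts, step = 1e-5, guard = 1e-3) {
  m <- length(counts)
  N <- sum(counts)
  p <- seq(guard, 1 - guard, by = step)
  E <- sapply(0:(m - 1), function(k) dbinom(k, m - 1, p))
  E <- pmax(E, 1e-9)
  NE <- N * E
  O <- matrix(counts, nrow(E), m, byrow = TRUE)
  chi2 <- rowSums((O - NE)^2 / NE)
  i <- which.min(chi2)
  list(p = p[i], chi2 = chi2[i])
}

# Longhand five-category binomial probabilities (m = 5 only).
oracle_binom5 <- function(p) {
  c((1 - p)^4,
    4 * p * (1 - p)^3,
    6 * p^2 * (1 - p)^2,
    4 * p^3 * (1 - p),
    p^4)
}

# Exact expected counts for a single binomial item.
expected_binomial_counts <- function(p, N, m = 5) {
  response_counts(N * dbinom(0:(m - 1), m - 1, p))
}

# Truncated-normal draw matching the generator's surrogate distribution.
draw_p_values <- function(n, mean = 0.56, sd = 0.13,
                          lower = 0.05, upper = 0.95) {
  qnorm(runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd)),
        mean, sd)
}
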