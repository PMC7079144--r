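# Independent oracles, written with explicit loops so they share no code
# path with the implementation they check.

# Brute-force normal equations for the MMSE lag coefficients: assemble
# A[i,k] = sum_j z[j-i] z[j-k] and b[i] = sum_j z[j-i] z[j+alpha] over every
# in-window alignment j, then solve. Only valid on full-rank problems.
brute_force_mmse <- function(z, m, alpha) {
  L <- length(z)
  js <- (m + 1):(L - alpha)
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (i in seq_len(m)) {
    for (k in seq_len(m)) {
      for (j in js) A[i, k] <- A[i, k] + z[j - i] * z[j - k]
    }
    for (j in js) b[i] <- b[i] + z[j - i] * z[j + alpha]
  }
  solve(A, b)
}

# Count rolling-forecast records by explicit enumeration of feasible
# origins (origin needs a full w-point history; target must lie in-series).
count_origins <- function(n, w, alpha) {
  count <- 0L
  for (o in seq_len(n)) {
    if (o >= w && o + alpha + 1L <= n) count <- count + 1L
  }
  count
}

# A strictly positive exact polynomial series (order <= 2), for exactness
# checks: any method with d >= its order must continue it perfectly.
exact_quadratic_series <- function(n, c0 = 500, c1 = 2, c2 = 0.1) {
  t <- seq_len(n) - 1
  c0 + c1 * t + c2 * t^2
}

# A positive synthetic 4-week-like series with mild noise, for generic
# property checks (not a demand emulation).
random_positive_series <- function(n, seed) {
  set.seed(seed)
  1000 + 30 * sin(2 * pi * seq_len(n) / 13) + stats::rnorm(n, sd = 20)
}
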