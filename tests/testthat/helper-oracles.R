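# Independent brute-force oracles used across tests. These deliberately use
# plain loops / direct definitions, not the package's vectorized code paths.

# sample entropy by direct template counting (Chebyshev distance,
# templates i = 1..n-m for both lengths, self-matches excluded)
brute_sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  A <- 0L; B <- 0L
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Shannon entropy by direct histogram counting
brute_shannon <- function(x, edges) {
  counts <- numeric(length(edges) - 1)
  for (v in x) {
    for (b in seq_len(length(edges) - 1)) {
      lo <- edges[b]; hi <- edges[b + 1]
      inside <- if (b < length(edges) - 1) v >= lo && v < hi else v >= lo && v <= hi
      if (inside) { counts[b] <- counts[b] + 1; break }
    }
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# H statistic of a two-group Kruskal-Wallis by the rank-sum definition
brute_kw_H <- function(g1, g2) {
  N <- length(g1) + length(g2)
  r <- rank(c(g1, g2))
  R1 <- sum(r[seq_along(g1)]); R2 <- sum(r[-seq_along(g1)])
  12 / (N * (N + 1)) * (R1^2 / length(g1) + R2^2 / length(g2)) - 3 * (N + 1)
}

# quick small synthetic session shared by several tests
quick_sim <- function(seed = 1, duration = 300, ...) {
  simulate_dyad(dyad_config(duration = duration, seed = seed, ...))
}
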