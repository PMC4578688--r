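# Shared independent oracles and fixture builders for the test suite.

# Random trend vector over {-1, 0, 1}.
rand_trend <- function(m, zero_ok = TRUE) {
  sym <- if (zero_ok) c(-1L, 0L, 1L) else c(-1L, 1L)
  sample(sym, m, replace = TRUE)
}

# Direct series summation of the product-chain variance:
# 4 phi1^2 (1 + 2 sum_k (b - c)^(2k)), truncated.
sigma2_series_oracle <- function(b, c, d, K = 200L) {
  phi1 <- d / (1 - b - c + 2 * d)
  4 * phi1^2 * (1 + 2 * sum((b - c)^(2 * (1:K))))
}

# Best positive-run score within the band: per diagonal, the classical
# maximum-subarray sum (empty run = 0).  Used to detect sign ties.
max_pos_run <- function(u, v, D) {
  m <- length(u)
  best <- 0L
  for (dl in (-D):D) {
    z <- if (dl >= 0L) u[seq_len(m - dl)] * v[seq_len(m - dl) + dl]
         else u[seq_len(m + dl) - dl] * v[seq_len(m + dl)]
    run <- 0L
    for (zi in z) {
      run <- max(0L, run + zi)
      if (run > best) best <- run
    }
  }
  best
}

# k-fold matrix multiplication oracle.
matpow <- function(T, k) {
  out <- diag(nrow(T))
  for (i in seq_len(k)) out <- out %*% T
  out
}

# Two-letter closed form T^k = (1/2) * (1 +- (-1)^k / 3^k).
two_letter_power_closed <- function(k) {
  e <- (-1)^k / 3^k
  matrix(c(1 + e, 1 - e, 1 - e, 1 + e) / 2, 2L, 2L, byrow = TRUE)
}
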