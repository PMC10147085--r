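# Naive reference implementations used as independent oracles.

# triple-loop PROMETHEE flows straight from the definitions
oracle_flows <- function(values, weights, directions, spec) {
  n <- nrow(values); k <- ncol(values)
  pi <- matrix(0, n, n)
  for (t in seq_len(n)) for (u in seq_len(n)) if (t != u) {
    acc <- 0
    for (j in seq_len(k)) {
      d <- directions[j] * (values[t, j] - values[u, j])
      acc <- acc + weights[j] * preference_value(d, spec)
    }
    pi[t, u] <- acc
  }
  list(pi = pi,
       plus = rowSums(pi) / (n - 1),
       minus = colSums(pi) / (n - 1))
}

# brute-force Kendall tau-b from concordant/discordant pair counts
oracle_tau_b <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

expect_flow_table_valid <- function(f) {
  expect_s3_class(f, "flow_table")
  expect_equal(f$phi_net, f$phi_plus - f$phi_minus, tolerance = 1e-12)
  expect_lt(abs(sum(f$phi_net)), 1e-9)
}
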