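# Shared small fixtures and oracles, built in code at test time.

fixture_samples <- list(c(1, 1), c(2, 2), c(3, 3), c(5, 1))
fixture_K <- c(0.5, 1, 2)

# Independent two-state oracle: transition probabilities of the chain
# with rates 1 (state 1 -> 2) and K (state 2 -> 1), by direct solution of
# the forward equations (eigen-decomposition by hand, not via expm).
two_state_p11 <- function(K, t) K / (1 + K) + exp(-(1 + K) * t) / (1 + K)

# Brute-force dual moment for tiny chains: enumerate expm row and sum
# moments (mirrors the definition; used as an oracle for t = 0 and the
# monotonicity property).
moment_of_row <- function(row, ss, x, y) {
  p <- function(b, e) if (e == 0) 1 else b^e
  sum(vapply(seq_len(ss$size), function(i)
    row[i] * p(x, ss$states$n[i]) * p(y, ss$states$m[i]), numeric(1)))
}

expect_rowsums_zero <- function(Q, tol = 1e-12) {
  expect_lt(max(abs(rowSums(unclass(Q)))), tol)
}
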