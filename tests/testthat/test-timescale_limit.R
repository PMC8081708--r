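test_that("matrix_norm is the maximum absolute row sum", {
  expect_equal(matrix_norm(diag(5)), 1)
  P <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(matrix_norm(P), 1)
  expect_equal(matrix_norm(P - diag(2)), 1.6)
})

test_that("discretise returns the exact one-step matrix with the expected leading order", {
  cc <- 0.1
  Q <- build_blockcounting_Q(sample_config(2, 0), model_params(cc, 1))
  Pi <- discretise(Q, cc^-2)
  expect_lt(max(abs(rowSums(Pi) - 1)), 1e-12)
  # coalescence entry: choose(2,2) c^2 up to the o(c^3) remainder
  expect_lt(abs(Pi["(2,0)", "(1,0)"] - cc^2), 1e-4)
  # a -> Inf: identity
  expect_equal(discretise(Q, 1e12), diag(nrow(Q)), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(discretise(Q, 0), "> 0")
})

test_that("decompose splits fast and slow transitions and reassembles exactly", {
  cc <- 0.1
  s <- sample_config(3, 1)
  ss <- state_space(s)
  Q <- build_blockcounting_Q(s, model_params(cc, 1))
  Pi <- discretise(Q, cc^-2)
  dec <- decompose(Pi, seedbank_fast_mask(ss), cc^-3)
  expect_lt(max(abs(dec$A + dec$B / dec$b - Pi)), 1e-14)
  expect_lt(max(abs(rowSums(dec$A) - 1)), 1e-12)
  # A keeps the fast coalescence mass: entry ((3,1),(2,1)) is
  # choose(3,2) c^2 up to the expansion remainder (second-order exponential
  # term, below c^3 at this c)
  expect_lt(abs(dec$A["(3,1)", "(2,1)"] - 3 * cc^2), cc^3)
  # B carries dormancy at rate n + o(1)
  expect_lt(abs(dec$B["(1,1)", "(0,2)"] - 1), 5 * cc)
  # a mask flagging everything makes A = Pi, B = 0
  all_mask <- matrix(TRUE, ss$size, ss$size)
  dec2 <- decompose(Pi, all_mask, cc^-3)
  expect_equal(dec2$A, Pi, ignore_attr = TRUE)
})

test_that("B entries approach the closed-form slow limit as c decreases", {
  s <- sample_config(2, 2)
  ss <- state_space(s)
  K <- 1.5
  Bl <- seedbank_B_limit(ss, K)
  # compare on rows whose slow targets all fit inside the enumeration grid
  # (boundary rows keep the printed diagonal in the closed form but lose
  # out-of-grid moves in the finite-c chain; they carry no mass from any
  # reachable start)
  keep <- ss$states$n < ss$nmax & ss$states$m < ss$nmax
  dev <- vapply(c(0.2, 0.1, 0.05), function(cc) {
    Pi <- discretise(build_blockcounting_Q(s, model_params(cc, K)), cc^-2)
    dec <- decompose(Pi, seedbank_fast_mask(ss), cc^-3)
    max(rowSums(abs((dec$B - Bl)[keep, , drop = FALSE])))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("projection extraction recovers the collapse to a single active line", {
  for (sm in list(c(3, 2), c(5, 1), c(2, 2))) {
    s <- sample_config(sm[1], sm[2])
    ss <- state_space(s)
    cc <- 0.05
    Q <- build_blockcounting_Q(s, model_params(cc, 1))
    dec <- decompose(discretise(Q, cc^-2), seedbank_fast_mask(ss), cc^-3)
    pr <- extract_projection(dec$A, cc^-2, C_grid = c(1, 10, 100))
    expect_identical(unname(pr$P), unname(build_aalp(s, 1)$P))
    expect_equal(pr$idempotency_dev, 0)
    # Markov bound on the norm decay: ||A^r - P|| <= 2 (n0 - 1) / C
    expect_true(all(pr$norm_decay <= 2 * (sm[1] - 1) / pr$C_grid))
  }
})

test_that("extract_projection fails loudly without stabilisation", {
  # a 2-state chain that keeps oscillating mass: no projection limit
  A <- matrix(c(0.5, 0.5, 0.5, 0.5) + c(0.2, -0.2, -0.2, 0.2), 2, 2)
  expect_error(extract_projection(A, a = 10, C_grid = c(1, 2)),
               "no stabilisation")
})

test_that("limit generator equals the closed forms for both models", {
  for (sm in fixture_samples) for (K in fixture_K) {
    s <- sample_config(sm[1], sm[2])
    ss <- state_space(s)
    aalp <- build_aalp(s, K)
    lg <- limit_generator(aalp$P, B_limit = seedbank_B_limit(ss, K))
    expect_identical(unname(lg$G), unname(aalp$G))
    hat <- build_imbalanced_limit(s, K)
    lg2 <- limit_generator(hat$P, B_limit = structured_B_limit(ss, K))
    expect_identical(unname(lg2$G), unname(hat$G))
    expect_equal(max(abs(aalp$P %*% aalp$G - aalp$G)), 0)
    expect_equal(max(abs(aalp$G %*% aalp$P - aalp$G)), 0)
  }
})

test_that("P B P sequence along a schedule is detected as Cauchy at a matched tolerance", {
  s <- sample_config(2, 2)
  ss <- state_space(s)
  K <- 1
  sched <- scaling_schedule(c(0.02, 0.01, 0.005))
  B_seq <- lapply(seq_along(sched$c_seq), function(i) {
    Pi <- discretise(build_blockcounting_Q(s, model_params(sched$c_seq[i], K)),
                     sched$a_seq[i])
    decompose(Pi, seedbank_fast_mask(ss), sched$b_seq[i])$B
  })
  P <- build_aalp(s, K)$P
  lg <- limit_generator(P, B_seq = B_seq, tol = 0.1)
  expect_true(lg$converged)
  expect_true(all(diff(lg$cauchy_gaps) < 0))
  # successive gaps shrink like c, far above the strict default tolerance
  expect_error(limit_generator(P, B_seq = B_seq, tol = 1e-8), "not Cauchy")
})

test_that("degenerate semigroup: projection at 0+, Chapman-Kolmogorov, stochastic rows", {
  a <- build_aalp(sample_config(3, 2), K = 2)
  expect_equal(degenerate_semigroup(a$P, a$G, 0), diag(nrow(a$P)),
               ignore_attr = TRUE)
  # t down to 0 gives P, not the identity
  expect_lt(max(abs(degenerate_semigroup(a$P, a$G, 1e-9) - a$P)), 1e-7)
  s <- degenerate_semigroup(a$P, a$G, 0.3)
  t <- degenerate_semigroup(a$P, a$G, 0.9)
  st <- degenerate_semigroup(a$P, a$G, 1.2)
  expect_lt(max(abs(s %*% t - st)), 1e-10)
  # rows with n = 0, or n >= 1 and m below the grid edge, are probability vectors
  ss <- a$ss
  good <- ss$states$n == 0 | ss$states$m < ss$nmax
  for (tt in c(0.01, 0.1, 1, 10)) {
    Pi_t <- degenerate_semigroup(a$P, a$G, tt)
    expect_lt(max(abs(rowSums(Pi_t)[good] - 1)), 1e-10)
    expect_gte(min(Pi_t[good, ]), -1e-12)
  }
  expect_error(degenerate_semigroup(a$P, a$G, -1), ">= 0")
  G_bad <- a$G
  G_bad["(2,1)", "(2,1)"] <- G_bad["(2,1)", "(2,1)"] - 1  # breaks PG = G
  expect_error(degenerate_semigroup(a$P, G_bad, 1), "PG = GP = G")
})

test_that("discretised powers converge to the degenerate semigroup", {
  s <- sample_config(2, 2)
  ss <- state_space(s)
  K <- 1
  aalp <- build_aalp(s, K)
  lim <- aalp_semigroup(aalp, 1)
  dev <- vapply(c(0.2, 0.1, 0.05), function(cc) {
    Pi <- discretise(build_blockcounting_Q(s, model_params(cc, K)), cc^-2)
    matrix_norm(seedbanklim:::mat_power(Pi, floor(cc^-3)) - lim)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("exit-rate ratio diagnostics separate shrinking from constant scales", {
  s <- sample_config(2, 2)
  c_seq <- c(0.2, 0.1, 0.05, 0.01)
  Q_seq <- lapply(c_seq, function(cc)
    build_blockcounting_Q(s, model_params(cc, 1)))
  chk <- check_exit_rate_ratio(Q_seq, c_seq^-2)
  expect_true(chk$ok)
  expect_true(all(diff(chk$ratio) < 0))
  # bound at c = 0.1: q <= choose(4,2) + c*4 + c*K*4
  expect_lte(chk$q_seq[2], 6 + 0.1 * 4 + 0.1 * 4)
  # negative control: constant rates and constant scale
  flat <- check_exit_rate_ratio(Q_seq[c(1, 1, 1)], rep(1, 3))
  expect_false(flat$ok)
})

test_that("scaling_schedule validates monotonicity and derives the scales", {
  sch <- scaling_schedule(c(0.2, 0.1))
  expect_equal(sch$a_seq, c(25, 100))
  expect_equal(sch$b_seq, c(125, 1000))
  expect_error(scaling_schedule(c(0.1, 0.2)), "decreasing")
})
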