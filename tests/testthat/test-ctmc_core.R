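test_that("block-counting rates match the model's event rates", {
  p <- model_params(c = 1, K = 1)
  Q <- build_blockcounting_Q(sample_config(2, 0), p)
  expect_equal(Q["(2,0)", "(1,0)"], 1)            # choose(2, 2) coalescence
  expect_equal(Q["(2,0)", "(1,1)"], 2)            # c * n dormancy
  expect_equal(unname(rowSums(unclass(Q))["(0,0)"]), 0)  # no lineages left
  expect_true(all(unclass(Q)["(0,0)", ] == 0))

  Q2 <- build_blockcounting_Q(sample_config(1, 0), model_params(0.5, 1))
  expect_equal(Q2["(1,0)", "(0,1)"], 0.5)         # c * n with n = 1

  # resuscitation and the K scaling
  Q3 <- build_blockcounting_Q(sample_config(1, 3), model_params(0.5, 2))
  expect_equal(Q3["(1,3)", "(2,2)"], 0.5 * 2 * 3) # c * K * m
})

test_that("structured rates add island-2 coalescence and reduce to the seed bank chain", {
  s <- sample_config(0, 3)
  Q <- build_structured_Q(s, model_params(1, 1, alpha = 1, alpha_prime = 1))
  expect_equal(Q["(0,3)", "(0,2)"], 3)            # choose(3, 2)

  # alpha' = 0, alpha = 1 is term-by-term the seed bank chain
  for (sm in fixture_samples) {
    s <- sample_config(sm[1], sm[2])
    Qs <- build_structured_Q(s, model_params(0.3, 2, 1, 0))
    Qb <- build_blockcounting_Q(s, model_params(0.3, 2))
    expect_identical(unclass(Qs), unclass(Qb))
  }
})

test_that("every rate matrix is conservative with non-negative off-diagonals", {
  for (sm in fixture_samples) for (cc in c(0.05, 1)) for (K in fixture_K) {
    Q <- build_structured_Q(sample_config(sm[1], sm[2]),
                            model_params(cc, K, alpha = 2, alpha_prime = 0.7))
    M <- unclass(Q)
    diag(M) <- 0
    expect_gte(min(M), 0)
    expect_rowsums_zero(Q)
  }
})

test_that("invalid parameters and samples are rejected", {
  expect_error(model_params(0, 1), "must be > 0")
  expect_error(model_params(1, -1), "must be > 0")
  expect_error(sample_config(0, 0), "at least one lineage")
  expect_error(transition_matrix(matrix(0, 2, 2), -1), ">= 0")
})

test_that("transition_matrix is the exact semigroup", {
  Q <- build_blockcounting_Q(sample_config(2, 1), model_params(0.7, 1.3))
  expect_equal(transition_matrix(Q, 0), diag(nrow(Q)), ignore_attr = TRUE)
  for (t in c(0.1, 1, 10))
    expect_lt(max(abs(rowSums(transition_matrix(Q, t)) - 1)), 1e-12)

  # two-state chain against the hand-solved forward equations
  K <- 1.7
  Q2 <- matrix(c(-1, 1, K, -K), 2, 2, byrow = TRUE)
  for (t in c(0.2, 1, 4))
    expect_equal(transition_matrix(Q2, t)[1, 1], two_state_p11(K, t),
                 tolerance = 1e-12)
})

test_that("gillespie paths are reproducible, monotone in total count, and absorb cleanly", {
  Q <- build_blockcounting_Q(sample_config(3, 2), model_params(0.5, 1))
  set.seed(42)
  p1 <- gillespie_simulate(Q, c(3, 2), horizon = 50)
  set.seed(42)
  p2 <- gillespie_simulate(Q, c(3, 2), horizon = 50)
  expect_identical(p1, p2)
  expect_identical(p1$times[1], 0)
  expect_equal(length(p1$times), nrow(p1$states))
  # total lineage count never increases (coalescence decreases, switching preserves)
  tot <- rowSums(p1$states)
  expect_true(all(diff(tot) <= 0))
  # consecutive states differ
  expect_true(all(rowSums(abs(diff(p1$states))) > 0))

  # absorbing start: no events ever
  p0 <- gillespie_simulate(Q, c(0, 0), horizon = 10)
  expect_identical(p0$times, 0)
  expect_identical(unname(p0$states[1, ]), c(0L, 0L))
})

test_that("first-jump competition matches the exponential race", {
  cc <- 0.8
  Q <- build_blockcounting_Q(sample_config(2, 0), model_params(cc, 1))
  # freeze the chain after its first event so only the race matters
  ss <- attr(Q, "state_space")
  Qf <- unclass(Q)
  Qf[-state_index(ss, 2, 0), ] <- 0
  attr(Qf, "state_space") <- ss
  reps <- 1e4
  set.seed(7)
  tables <- seedbanklim:::jump_tables(Qf)
  first <- vapply(seq_len(reps), function(i) {
    p <- gillespie_simulate(Qf, c(2, 0), horizon = 1000, tables = tables)
    paste(p$states[nrow(p$states), ], collapse = ",")
  }, character(1))
  p_coal <- 1 / (1 + 2 * cc)   # choose(2,2) vs dormancy rate 2c
  phat <- mean(first == "1,0")
  expect_lt(abs(phat - p_coal), 4 * sqrt(p_coal * (1 - p_coal) / reps))
})

test_that("time-t marginals agree with the matrix exponential", {
  Q <- build_blockcounting_Q(sample_config(2, 1), model_params(0.6, 1.5))
  ss <- attr(Q, "state_space")
  reps <- 1e4
  set.seed(8)
  idx <- simulate_ctmc_marginal(Q, c(2, 1), t = 1, reps = reps)
  counts <- tabulate(idx, nbins = ss$size)
  exact <- transition_matrix(Q, 1)[state_index(ss, 2, 1), ]
  expect_lt(tv_distance(counts, exact), 0.03)
})

test_that("matrices and paths round-trip through their serialised forms", {
  Q <- build_blockcounting_Q(sample_config(2, 1), model_params(0.3, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_matrix_json(Q, f)
  back <- read_matrix_json(f)
  expect_equal(unname(back), unname(unclass(Q)), ignore_attr = TRUE)
  expect_true(all(back == unclass(Q)))   # bit-faithful entries
  expect_rowsums_zero(back)

  set.seed(1)
  p <- gillespie_simulate(Q, c(2, 1), horizon = 10)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_jump_paths_csv(p, fcsv)
  df <- utils::read.csv(fcsv)
  expect_identical(names(df), c("replicate", "time", "n", "m"))
  expect_identical(df$time, p$times)
  expect_true(all(diff(df$time) > 0))
})
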