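test_that("degenerate starts never jump and the path structure is valid", {
  set.seed(1)
  p <- simulate_limit_pdmp(c(1, 1), K = 1, horizon = 100)
  expect_true(p$absorbed)
  expect_identical(nrow(p$jumps), 0L)
  st <- evaluate_pdmp(p, c(0, 1, 50))
  expect_true(all(st$x == 1) && all(st$y == 1))

  set.seed(2)
  q <- simulate_limit_pdmp(c(0.5, 0.9), K = 2, horizon = 20)
  if (nrow(q$jumps) > 0) {
    expect_true(all(diff(c(0, q$jumps$time)) > 0))
    # x alternates 0 <-> 1 along the skeleton
    xs <- c(q$x0_plus, q$jumps$x_new)
    expect_true(all(abs(diff(xs)) == 1))
  }
})

test_that("the dormant frequency relaxes exponentially and is continuous at jumps", {
  set.seed(5)
  # force the no-jump branch: from (0, y) the hazard is y e^{-Kt}
  K <- 2
  repeat {
    p <- simulate_limit_pdmp(c(0, 0.8), K, horizon = 3)
    if (nrow(p$jumps) == 0) break
  }
  st <- evaluate_pdmp(p, c(0.5, 0.5 + log(2) / K))
  expect_equal(st$y[2], st$y[1] / 2, tolerance = 1e-12)  # halves per ln2/K

  # continuity across a recorded jump
  set.seed(8)
  repeat {
    p <- simulate_limit_pdmp(c(0, 0.9), K = 1, horizon = 10)
    if (nrow(p$jumps) >= 1) break
  }
  tj <- p$jumps$time[1]
  eps <- 1e-9
  before <- evaluate_pdmp(p, tj - eps)$y
  after <- evaluate_pdmp(p, tj + eps)$y
  expect_lt(abs(before - after), 1e-6)
})

test_that("the probability of never flipping matches the closed-form total hazard", {
  # from x = 1, y = 0 the total future hazard is 1/K
  for (K in c(0.8, 2)) {
    reps <- 4000
    set.seed(100 + K)
    none <- mean(vapply(seq_len(reps), function(i)
      nrow(simulate_limit_pdmp(c(1, 0), K, horizon = Inf)$jumps) == 0,
      logical(1)))
    p0 <- exp(-1 / K)
    expect_lt(abs(none - p0), 4 * sqrt(p0 * (1 - p0) / reps))
  }
})

test_that("the initial Bernoulli randomisation reproduces the fixation law at 0+", {
  reps <- 1e4
  set.seed(12)
  mar <- pdmp_marginal(c(0.3, 0.8), K = 1, t_grid = 1e-8, reps = reps)
  expect_true(all(mar$x %in% c(0, 1)))
  expect_lt(abs(mean(mar$x) - 0.3), 4 * sqrt(0.3 * 0.7 / reps))
})

test_that("jump-process moments agree with the telegraph closed form", {
  set.seed(21)
  pm <- pdmp_moments(c(1, 0), K = 1, t = 50, n = 1, m = 0, reps = 4000)
  expect_equal(pm$exact, 0.5, tolerance = 1e-6)      # stationary K/(1+K)
  expect_lt(abs(pm$estimate - pm$exact), 4 * pm$se)
  pm0 <- pdmp_moments(c(0.4, 0.2), K = 1, t = 1, n = 0, m = 0, reps = 10)
  expect_identical(pm0$estimate, 1)
})

test_that("the weighted frequency K X + Y is conserved by the exact jump process", {
  reps <- 1e4
  K <- 1.5
  set.seed(33)
  mar <- pdmp_marginal(c(0.3, 0.7), K, t_grid = 1, reps = reps)
  w <- K * mar$x[, 1] + mar$y[, 1]
  expect_lt(abs(mean(w) - (K * 0.3 + 0.7)), 4 * sd(w) / sqrt(reps))
})

test_that("generator duality: both generators act identically on mixed moments", {
  # A S_{n,m}(x, y) for the jump process versus the reduced chain's
  # Q-matrix acting on (n, m) -> x^n y^m, evaluated entrywise.
  pw <- function(b, e) if (e == 0) 1 else b^e
  gen_forward <- function(x, y, n, m, K) {
    S <- function(x_, y_) pw(x_, n) * pw(y_, m)
    dS <- if (m == 0) 0 else pw(x, n) * m * y^(m - 1)
    (1 - x) * y * (S(1, y) - S(x, y)) +
      x * (1 - y) * (S(0, y) - S(x, y)) + K * (x - y) * dS
  }
  gen_backward <- function(x, y, n, m, K) {
    S <- function(n_, m_) pw(x, n_) * pw(y, m_)
    (if (m >= 1) K * m * (S(1, m - 1) - S(n, m)) else 0) +
      (if (n == 1) S(0, m + 1) - S(n, m) else 0)
  }
  worst <- 0
  for (K in c(0.5, 1, 2)) for (x in c(0, 1))
    for (y in seq(0, 1, length.out = 21))
      for (n in 0:1) for (m in 0:4)
        worst <- max(worst, abs(gen_forward(x, y, n, m, K) -
                                  gen_backward(x, y, n, m, K)))
  expect_lt(worst, 1e-12)
})

test_that("the limit jump-diffusion conserves K X + Y and respects its guards", {
  reps <- 1e4
  K <- 1.5
  cfg <- em_config(dt = 1e-3, horizon = 1, reps = reps, seed = 77,
                   record_times = 1)
  set.seed(77)
  g <- simulate_limit_jumpdiffusion(c(0.3, 0.7), K, cfg)
  expect_true(all(g$x %in% c(0, 1)))
  w <- K * g$x[, 1] + g$y[, 1]
  expect_lt(abs(mean(w) - (K * 0.3 + 0.7)), 4 * sd(w) / sqrt(reps))
  set.seed(1)
  g1 <- simulate_limit_jumpdiffusion(c(1, 1), K,
                                     em_config(dt = 1e-3, horizon = 0.5,
                                               reps = 10, seed = 1,
                                               record_times = 0.5))
  expect_true(all(g1$x == 1) && all(g1$y == 1))
  expect_error(simulate_limit_jumpdiffusion(
    c(0.3, 0.7), K, em_config(dt = 0.2, horizon = 1, reps = 1, seed = 1,
                              record_times = 1)),
    "thinning")
})

test_that("halving the step changes jump-diffusion moments by less than the Monte-Carlo error", {
  reps <- 1e4
  K <- 1
  est <- vapply(c(2e-3, 1e-3), function(dt) {
    set.seed(41)
    g <- simulate_limit_jumpdiffusion(
      c(0.3, 0.7), K, em_config(dt = dt, horizon = 1, reps = reps,
                                seed = 41, record_times = 1))
    mean(g$y[, 1])
  }, numeric(1))
  expect_lt(abs(diff(est)), 2 * 0.5 / sqrt(reps) * 2)
})
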