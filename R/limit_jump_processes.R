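## Exact simulation of the super-evolutionary forward limits.  In the limit
## the active frequency X lives on {0, 1} and flips at a hazard given by the
## dormant frequency (rate Y from 0, rate 1 - Y from 1), while between jumps
## Y relaxes exponentially towards X at rate K.  Because Y's flow is an
## explicit exponential, the cumulative jump hazard has a closed form and
## jump times can be drawn by exact inversion -- no discretisation error.
## The two-island variant keeps a diffusive Y and is simulated by
## Euler-Maruyama with per-step thinning for the X flips.

#' Simulate the limiting jump process of the seed bank diffusion
#'
#' Exact simulation of the piecewise-deterministic limit: at time `0+` the
#' active component jumps to 1 with probability `x0` and to 0 otherwise
#' (the fixation probabilities of the instantaneous Wright-Fisher sweep);
#' thereafter, in state `x`, the flip hazard at time `t` is the dormant
#' frequency `Y(t)` (if `x = 0`) or `1 - Y(t)` (if `x = 1`), while
#' `Y(t) = x + (y_last - x) * exp(-K (t - t_last))` relaxes towards `x`.
#' With initial hazard `h0 = |y - x|`, the total remaining hazard is
#' `h0 / K`; an `Exp(1)` draw `E >= h0 / K` means the path never flips
#' again (it is absorbed and `Y` relaxes to `x` forever), otherwise the
#' next flip happens after `-log(1 - K E / h0) / K` and `Y` is continuous
#' across it.
#'
#' @param start numeric length-2 vector `(x0, y0)` in `[0, 1]^2`.
#' @param K size ratio, positive.
#' @param horizon non-negative time at which the path is truncated.
#' @return An object of class `"pdmp_path"`: list with `initial` (the raw
#'   `(x0, y0)` reported at `t = 0`), `x0_plus` (the Bernoulli outcome at
#'   `0+`), `jumps` (data frame `time`, `x_new`, `y_at_jump`), `absorbed`,
#'   `K`, `horizon`.
#' @examples
#' set.seed(2)
#' p <- simulate_limit_pdmp(c(0.3, 0.8), K = 1, horizon = 5)
#' evaluate_pdmp(p, c(0, 1e-8, 1, 5))
#' @export
simulate_limit_pdmp <- function(start, K, horizon) {
  stopifnot(is.numeric(start), length(start) == 2L,
            all(start >= 0), all(start <= 1), K > 0, horizon >= 0)
  x <- as.numeric(stats::rbinom(1L, 1L, start[1]))
  x0_plus <- x
  y <- start[2]
  t_now <- 0
  jt <- numeric(0)
  jx <- numeric(0)
  jy <- numeric(0)
  absorbed <- FALSE
  repeat {
    h0 <- abs(y - x)                # initial hazard |Y - x| decays exp(-Kt)
    if (h0 <= 0) { absorbed <- TRUE; break }
    E <- stats::rexp(1L)
    if (E >= h0 / K) { absorbed <- TRUE; break }
    tau <- -log(1 - K * E / h0) / K
    if (t_now + tau > horizon) break
    t_now <- t_now + tau
    y <- x + (y - x) * exp(-K * tau)   # flow up to the jump; continuous
    x <- 1 - x
    jt <- c(jt, t_now)
    jx <- c(jx, x)
    jy <- c(jy, y)
  }
  structure(list(initial = c(x = start[1], y = start[2]),
                 x0_plus = x0_plus,
                 jumps = data.frame(time = jt, x_new = jx, y_at_jump = jy),
                 absorbed = absorbed, K = K, horizon = horizon),
            class = "pdmp_path")
}

#' @export
print.pdmp_path <- function(x, ...) {
  cat(sprintf(
    "pdmp_path: X(0+) = %g, %d flips on [0, %g]%s\n", x$x0_plus,
    nrow(x$jumps), x$horizon, if (x$absorbed) ", absorbed" else ""))
  invisible(x)
}

#' Evaluate a jump-process path on a time grid
#'
#' Closed-form evaluation between jumps: `X` is right-continuous and
#' piecewise constant, `Y(t) = x + (y_seg - x) * exp(-K (t - t_seg))`.
#' At `t = 0` the raw initial state is returned (the binary `X` appears
#' from `0+`, mirroring the semigroup structure where `Pi(0)` is the
#' identity but `Pi(0+)` is the projection).
#'
#' @param path a `"pdmp_path"`.
#' @param t_grid non-negative times within the path's horizon.
#' @return A data frame with columns `t`, `x`, `y`.
#' @export
evaluate_pdmp <- function(path, t_grid) {
  stopifnot(inherits(path, "pdmp_path"), all(t_grid >= 0),
            all(t_grid <= path$horizon + 1e-12))
  K <- path$K
  jumps <- path$jumps
  seg_t <- c(0, jumps$time)
  seg_x <- c(path$x0_plus, jumps$x_new)
  seg_y <- c(path$initial[["y"]], jumps$y_at_jump)
  out_x <- numeric(length(t_grid))
  out_y <- numeric(length(t_grid))
  for (i in seq_along(t_grid)) {
    t <- t_grid[i]
    if (t == 0) {
      out_x[i] <- path$initial[["x"]]
      out_y[i] <- path$initial[["y"]]
      next
    }
    k <- findInterval(t, seg_t)
    x <- seg_x[k]
    out_x[i] <- x
    out_y[i] <- x + (seg_y[k] - x) * exp(-K * (t - seg_t[k]))
  }
  data.frame(t = t_grid, x = out_x, y = out_y)
}

#' Monte-Carlo mixed moments of the limiting jump process
#'
#' Estimates `E[X(t)^n Y(t)^m]` from `reps` exactly simulated paths (with
#' the `0^0 = 1` convention).  For `m = 0` and `n >= 1` the exact value
#' `x * p11(t) + y * p10(t)` from [telegraph_closed_form()] is returned
#' alongside: once a single line remains, the dual genealogy is the
#' two-state telegraph chain and the moment no longer depends on `n`.
#'
#' @param start numeric length-2 vector in `[0, 1]^2`.
#' @param K size ratio.
#' @param t observation time.
#' @param n,m non-negative integer exponents.
#' @param reps number of replicates.
#' @return List with `estimate`, `se`, `reps` and (when available)
#'   `exact`.
#' @export
pdmp_moments <- function(start, K, t, n, m, reps) {
  stopifnot(n >= 0, m >= 0, reps >= 1)
  mar <- pdmp_marginal(start, K, t, reps)
  vals <- pow00(mar$x[, 1], n) * pow00(mar$y[, 1], m)
  est <- mean(vals)
  se <- stats::sd(vals) / sqrt(reps)
  exact <- if (m == 0 && n >= 1) {
    tc <- telegraph_closed_form(K, t)
    start[1] * tc$p11 + start[2] * tc$p10
  } else if (n == 0 && m == 0) 1 else NULL
  out <- list(estimate = est, se = se, reps = reps)
  if (!is.null(exact)) out$exact <- exact
  out
}

## x^n with 0^0 = 1, vectorised in x
pow00 <- function(x, n) if (n == 0) rep(1, length(x)) else x^n

## One weak Euler step on [0,1] with conditional mean mu and variance s2,
## vectorised over replicates.  Mirrors the compiled kernel: Gaussian in
## the interior, a mean- and variance-matched two-point increment within
## 4 standard deviations of either boundary (clamping there would inject
## a dt-independent boundary-layer bias).
em_step01 <- function(mu, s2, reps) {
  s <- sqrt(pmax(0, s2))
  out <- pmin(1, pmax(0, mu + s * stats::rnorm(reps)))
  lo <- s2 > 0 & mu < 4 * s
  hi <- !lo & s2 > 0 & (1 - mu) < 4 * s
  if (any(lo)) {
    m <- pmax(mu[lo], 0)
    p <- ifelse(m > 0, m^2 / (m^2 + s2[lo]), 0)
    out[lo] <- ifelse(stats::runif(sum(lo)) < p, m + s2[lo] / pmax(m, 1e-300), 0)
  }
  if (any(hi)) {
    d <- pmax(1 - mu[hi], 0)
    q <- ifelse(d > 0, d^2 / (d^2 + s2[hi]), 0)
    out[hi] <- ifelse(stats::runif(sum(hi)) < q, 1 - d - s2[hi] / pmax(d, 1e-300), 1)
  }
  out
}

#' Time-marginal sample of the limiting jump process
#'
#' Draws `reps` exact paths and evaluates `(X, Y)` at each time in
#' `t_grid`, without storing the paths.  Jump times use the same exact
#' hazard inversion as [simulate_limit_pdmp()].
#'
#' @inheritParams pdmp_moments
#' @param t_grid non-negative observation times (each `> 0` sees the
#'   post-projection binary `X`).
#' @return List with matrices `x`, `y` of dimension
#'   `reps x length(t_grid)`.
#' @export
pdmp_marginal <- function(start, K, t_grid, reps) {
  stopifnot(all(t_grid >= 0), reps >= 1, K > 0)
  t_grid <- as.numeric(t_grid)
  horizon <- max(t_grid)
  X <- matrix(NA_real_, reps, length(t_grid))
  Y <- matrix(NA_real_, reps, length(t_grid))
  init_x <- as.numeric(stats::rbinom(reps, 1L, start[1]))
  for (r in seq_len(reps)) {
    x <- init_x[r]
    y <- start[2]
    t_seg <- 0
    remaining <- order(t_grid)
    pos <- 1L
    repeat {
      h0 <- abs(y - x)
      tau <- if (h0 <= 0) Inf else {
        E <- stats::rexp(1L)
        if (E >= h0 / K) Inf else -log(1 - K * E / h0) / K
      }
      t_jump <- t_seg + tau
      while (pos <= length(remaining) &&
             t_grid[remaining[pos]] <= min(t_jump, horizon)) {
        i <- remaining[pos]
        t <- t_grid[i]
        if (t == 0) {
          X[r, i] <- start[1]
          Y[r, i] <- start[2]
        } else {
          X[r, i] <- x
          Y[r, i] <- x + (y - x) * exp(-K * (t - t_seg))
        }
        pos <- pos + 1L
      }
      if (t_jump > horizon) break
      y <- x + (y - x) * exp(-K * tau)
      x <- 1 - x
      t_seg <- t_jump
    }
  }
  list(x = X, y = Y)
}

#' Simulate the two-island limit jump-diffusion
#'
#' Hybrid scheme for the limit in which island 2 keeps genuine reproduction:
#' `Y` follows Euler-Maruyama with drift `K (X - Y)` and diffusion
#' coefficient `sqrt(max(0, y (1 - y)))` (clamped to `[0, 1]`), while the
#' binary `X` flips by per-step thinning with probability
#' `lambda * dt`, `lambda = y` in state 0 and `1 - y` in state 1.  The
#' initial Bernoulli randomisation of `X(0+)` is as in
#' [simulate_limit_pdmp()].  Draws come from R's global RNG.
#'
#' @param start numeric length-2 vector in `[0, 1]^2`.
#' @param K size ratio.
#' @param cfg an [em_config()]; `dt * 1` (the maximal hazard) must stay
#'   below 0.1 for the thinning to be a faithful approximation.
#' @return A `"path_grid"` with binary `x` entries.
#' @export
simulate_limit_jumpdiffusion <- function(start, K, cfg) {
  stopifnot(inherits(cfg, "em_config"),
            is.numeric(start), length(start) == 2L,
            all(start >= 0), all(start <= 1), K > 0)
  if (cfg$dt * 1 >= 0.1)
    stop("dt * max hazard >= 0.1: thinning approximation invalid; reduce dt")
  reps <- cfg$reps
  record_steps <- as.integer(round(cfg$record_times / cfg$dt))
  nsteps <- max(record_steps)
  x <- as.numeric(stats::rbinom(reps, 1L, start[1]))
  y <- rep(start[2], reps)
  sqdt <- sqrt(cfg$dt)
  X <- matrix(NA_real_, reps, length(record_steps))
  Y <- matrix(NA_real_, reps, length(record_steps))
  k <- 1L
  while (k <= length(record_steps) && record_steps[k] == 0L) {
    X[, k] <- start[1]          # t = 0 reports the raw initial state
    Y[, k] <- start[2]
    k <- k + 1L
  }
  for (step in seq_len(nsteps)) {
    lambda <- ifelse(x == 1, 1 - y, y)
    flip <- stats::runif(reps) < lambda * cfg$dt
    y <- em_step01(y + K * (x - y) * cfg$dt, y * (1 - y) * cfg$dt, reps)
    x <- ifelse(flip, 1 - x, x)
    while (k <= length(record_steps) && record_steps[k] == step) {
      X[, k] <- x
      Y[, k] <- y
      k <- k + 1L
    }
  }
  new_path_grid(record_steps * cfg$dt, X, Y, "two-island limit jump-diffusion")
}
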