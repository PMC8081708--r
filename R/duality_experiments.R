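## The verification engine: exact dual expectations from matrix
## exponentials, Monte-Carlo forward moments, duality reports with a
## 4-standard-error pass rule, and the scripted convergence experiments
## linking the prelimit processes to their super-evolutionary limits.

#' Exact dual expectation of a mixed moment
#'
#' Computes `E[x^N(t) y^M(t)]` for a block-counting chain started at
#' `(n, m)`: the `(n, m)` row of `expm(t Q)` integrated against the mixed
#' moment `x^nbar y^mbar` (with the `0^0 = 1` convention).  By moment
#' duality this equals the forward moment `E[X(t)^n Y(t)^m]` of the
#' matching diffusion started at `(x, y)`.
#'
#' @param n,m non-negative integers, the dual chain's start (and the
#'   forward moment's exponents).
#' @param x,y numbers in `[0, 1]`, the diffusion's start.
#' @param t non-negative time.
#' @param Q rate matrix of the dual chain; built on the fly via
#'   [build_blockcounting_Q()] when omitted, in which case `params` must be
#'   given.
#' @param params a [model_params()] (used only when `Q` is missing).
#' @return A single number in `[0, 1]`.
#' @examples
#' dual_moment_exact(2, 1, 0.3, 0.7, 0.5, params = model_params(1, 2))
#' @export
dual_moment_exact <- function(n, m, x, y, t, Q = NULL, params = NULL) {
  stopifnot(n >= 0, m >= 0, x >= 0, x <= 1, y >= 0, y <= 1)
  if (t < 0) stop("time 't' must be >= 0")
  if (n == 0 && m == 0) return(1)   # no lineages: the dual chain is frozen
  if (is.null(Q)) {
    stopifnot(inherits(params, "model_params"))
    Q <- build_blockcounting_Q(sample_config(n, m), params)
  }
  ss <- attr(Q, "state_space")
  stopifnot(!is.null(ss), n <= ss$nmax, m <= ss$nmax)
  row <- transition_matrix(Q, t)[state_index(ss, n, m), ]
  moments <- vapply(seq_len(ss$size), function(i)
    pow00(x, ss$states$n[i]) * pow00(y, ss$states$m[i]), numeric(1))
  sum(row * moments)
}

new_duality_report <- function(exact, estimate, se, reps, bias_allowance,
                               label) {
  tol <- 4 * se + bias_allowance
  dev <- estimate - exact
  z <- if (se > 0) dev / se else if (abs(dev) <= bias_allowance) 0 else Inf
  structure(list(exact = exact, estimate = estimate, se = se, reps = reps,
                 z = z, tolerance = tol,
                 pass = abs(estimate - exact) <= tol, label = label),
            class = "duality_report")
}

#' @export
print.duality_report <- function(x, ...) {
  cat(sprintf(
    "duality_report [%s]\n  exact %.6f  estimate %.6f (se %.2g, %d reps)\n  z = %.2f, tolerance %.4g -> %s\n",
    x$label, x$exact, x$estimate, x$se, x$reps, x$z, x$tolerance,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Moment-duality check for the seed bank diffusion
#'
#' Compares the exact dual expectation (backward in time, a matrix
#' exponential of the block-counting chain) against the forward Monte-Carlo
#' mean of `X(t)^n Y(t)^m` from [simulate_seedbank_sde()].  The pass rule
#' is `|estimate - exact| <= 4 * se + bias_allowance`, with the allowance
#' `C_bias * dt` covering the Euler-Maruyama discretisation bias
#' (`C_bias = 1` by default, calibrated once by a step-halving study).
#'
#' @param n,m non-negative integer moment exponents.
#' @param start numeric length-2 diffusion start `(x, y)`.
#' @param params a [model_params()].
#' @param t observation time.
#' @param cfg an [em_config()] (its `record_times` are overridden by `t`).
#' @param C_bias multiplier of `dt` in the bias allowance.
#' @return A `"duality_report"`.
#' @export
duality_check_seedbank <- function(n, m, start, params, t, cfg, C_bias = 1) {
  stopifnot(inherits(cfg, "em_config"))
  cfg <- em_config(dt = cfg$dt, horizon = t, reps = cfg$reps, seed = cfg$seed,
                   record_times = t)
  g <- simulate_seedbank_sde(start, params, cfg)
  vals <- pow00(g$x[, 1], n) * pow00(g$y[, 1], m)
  se <- stats::sd(vals) / sqrt(cfg$reps)
  if (se > 0.05)
    warning("Monte-Carlo standard error above 0.05; increase 'reps'")
  exact <- dual_moment_exact(n, m, start[1], start[2], t, params = params)
  new_duality_report(exact, mean(vals), se, cfg$reps,
                     bias_allowance = C_bias * cfg$dt,
                     label = sprintf("seed bank (n,m)=(%d,%d) c=%g K=%g t=%g",
                                     n, m, params$c, params$K, t))
}

#' Moment-duality check for the limiting jump process
#'
#' Backward side: `E[x^N y^M]` under the degenerate semigroup
#' `P exp(tG)` of the limit genealogy started at `(n, m)`.  Forward side:
#' Monte-Carlo mean of `X(t)^n Y(t)^m` over exactly simulated jump-process
#' paths ([pdmp_marginal()]).  No bias allowance: the jump times carry no
#' discretisation error.
#'
#' @inheritParams duality_check_seedbank
#' @param K size ratio.
#' @param reps number of replicates.
#' @return A `"duality_report"`.
#' @export
duality_check_limit <- function(n, m, start, K, t, reps) {
  aalp <- build_aalp(sample_config(max(n, 1L), max(m, 1L)), K)
  exact <- limit_dual_moment_exact(aalp, n, m, start[1], start[2], t)
  mar <- pdmp_marginal(start, K, t, reps)
  vals <- pow00(mar$x[, 1], n) * pow00(mar$y[, 1], m)
  se <- stats::sd(vals) / sqrt(reps)
  if (se > 0.05)
    warning("Monte-Carlo standard error above 0.05; increase 'reps'")
  new_duality_report(exact, mean(vals), se, reps, bias_allowance = 0,
                     label = sprintf("limit (n,m)=(%d,%d) K=%g t=%g",
                                     n, m, K, t))
}

#' Exact dual expectation under the degenerate limit semigroup
#'
#' `E[x^N(t) y^M(t)]` for the limit genealogy started at `(n, m)`,
#' integrated against `Pi(t) = P exp(tG)` (identity at `t = 0`).
#'
#' @param aalp an `"aalp"` whose grid contains `(n, m)`.
#' @param n,m non-negative integer start of the dual chain.
#' @param x,y numbers in `[0, 1]`.
#' @param t non-negative time.
#' @return A single number.
#' @export
limit_dual_moment_exact <- function(aalp, n, m, x, y, t) {
  stopifnot(inherits(aalp, "aalp"), n >= 0, m >= 0, t >= 0)
  ss <- aalp$ss
  stopifnot(n <= ss$nmax, m <= ss$nmax)
  row <- aalp_semigroup(aalp, t)[state_index(ss, n, m), ]
  moments <- vapply(seq_len(ss$size), function(i)
    pow00(x, ss$states$n[i]) * pow00(y, ss$states$m[i]), numeric(1))
  sum(row * moments)
}

#' Grid of seed bank duality checks sharing one forward simulation
#'
#' Runs [duality_check_seedbank()] over a grid of moment indices and times,
#' reusing a single forward simulation per `(c, K)` parameter cell (the
#' forward paths do not depend on the moment being read off).
#'
#' @param indices data frame (or 2-column matrix) of moment exponents with
#'   columns `n`, `m`.
#' @param start diffusion start `(x, y)`.
#' @param c_values,K_values parameter grids.
#' @param t_values observation times (all recorded from the same paths).
#' @param dt Euler-Maruyama step size.
#' @param reps replicates per parameter cell.
#' @param seed integer seed (each cell uses an offset sub-seed).
#' @param C_bias bias-allowance multiplier, see
#'   [duality_check_seedbank()].
#' @return A data frame with one row per grid cell and the
#'   `"duality_report"` fields as columns.
#' @export
duality_grid_seedbank <- function(indices, start, c_values, K_values,
                                  t_values, dt = 1e-3, reps = 2e4,
                                  seed = 1, C_bias = 1) {
  indices <- as.data.frame(indices)
  rows <- list()
  cell <- 0L
  for (cc in c_values) for (K in K_values) {
    cell <- cell + 1L
    params <- model_params(cc, K)
    cfg <- em_config(dt = dt, horizon = max(t_values), reps = reps,
                     seed = seed + cell * 1e6, record_times = t_values)
    g <- simulate_seedbank_sde(start, params, cfg)
    for (it in seq_along(t_values)) for (r in seq_len(nrow(indices))) {
      n <- indices$n[r]
      m <- indices$m[r]
      vals <- pow00(g$x[, it], n) * pow00(g$y[, it], m)
      se <- stats::sd(vals) / sqrt(reps)
      exact <- dual_moment_exact(n, m, start[1], start[2], t_values[it],
                                 params = params)
      rep_ <- new_duality_report(exact, mean(vals), se, reps,
                                 bias_allowance = C_bias * dt,
                                 label = sprintf("(%d,%d) c=%g K=%g t=%g",
                                                 n, m, cc, K, t_values[it]))
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, m = m, c = cc, K = K, t = t_values[it],
        exact = rep_$exact, estimate = rep_$estimate, se = rep_$se,
        z = rep_$z, tolerance = rep_$tolerance, pass = rep_$pass)
    }
  }
  do.call(rbind, rows)
}

#' Grid of limit duality checks sharing one jump-process simulation
#'
#' As [duality_grid_seedbank()] for the limit pair: exact side from
#' `P exp(tG)`, forward side from exact jump-process paths, no bias
#' allowance.
#'
#' @inheritParams duality_grid_seedbank
#' @param K_values size ratios.
#' @return A data frame of report rows.
#' @export
duality_grid_limit <- function(indices, start, K_values, t_values,
                               reps = 1e4) {
  indices <- as.data.frame(indices)
  nmax <- max(c(indices$n, 1))
  mmax <- max(c(indices$m, 1))
  rows <- list()
  for (K in K_values) {
    mar <- pdmp_marginal(start, K, t_values, reps)
    aalp <- build_aalp(sample_config(nmax, mmax), K)
    for (it in seq_along(t_values)) for (r in seq_len(nrow(indices))) {
      n <- indices$n[r]
      m <- indices$m[r]
      vals <- pow00(mar$x[, it], n) * pow00(mar$y[, it], m)
      se <- stats::sd(vals) / sqrt(reps)
      exact <- limit_dual_moment_exact(aalp, n, m, start[1], start[2],
                                       t_values[it])
      dev <- mean(vals) - exact
      z <- if (se > 0) dev / se else if (abs(dev) <= 1e-12) 0 else Inf
      # no discretisation bias term (jump times are exact); the 1e-12
      # covers only the matrix-exponential accuracy of the exact side
      tol <- 4 * se + 1e-12
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, m = m, K = K, t = t_values[it], exact = exact,
        estimate = mean(vals), se = se, z = z,
        tolerance = tol, pass = abs(dev) <= tol)
    }
  }
  do.call(rbind, rows)
}

#' Backward convergence experiment: prelimit chain to the limit genealogy
#'
#' For each migration rate `c` in the schedule, simulates the seed bank
#' block-counting chain to time `t / c` (the super-evolutionary
#' observation) and compares the empirical time-marginal against the
#' corresponding row of the limit semigroup `Pi(t) = P exp(tG)` in
#' total-variation distance over the full finite state space.
#'
#' @param sample a [sample_config()].
#' @param K size ratio.
#' @param schedule a [scaling_schedule()].
#' @param t observation time on the rescaled clock.
#' @param reps Gillespie replicates per schedule point.
#' @return An object of class `"convergence_report"`: list with
#'   `c_values`, `metric` (TV distances), `noise_floor`, `monotone` (per
#'   the one-inversion-within-noise rule) and `final`.
#' @export
convergence_experiment_backward <- function(sample, K, schedule, t, reps) {
  stopifnot(inherits(schedule, "scaling_schedule"))
  aalp <- build_aalp(sample, K)
  limit_row <- aalp_semigroup(aalp, t)[
    state_index(aalp$ss, sample$n0, sample$m0), ]
  tv <- vapply(schedule$c_seq, function(cc) {
    Q <- build_blockcounting_Q(sample, model_params(cc, K))
    idx <- simulate_ctmc_marginal(Q, c(sample$n0, sample$m0), t / cc, reps)
    counts <- tabulate(idx, nbins = aalp$ss$size)
    tv_distance(counts, limit_row)
  }, numeric(1))
  new_convergence_report(schedule$c_seq, tv, noise_floor = 1 / sqrt(reps))
}

#' Forward convergence experiment: rescaled diffusion to the jump process
#'
#' For each `c` in the schedule, simulates the seed bank diffusion on the
#' horizon `t / c` and reports the gaps `|E^[X^c(t/c)] - E[X~(t)]|` and
#' `|E^[Y^c(t/c)] - E[Y~(t)]|`, with the limit moments taken from the
#' closed telegraph form (for `X`) and from the limit semigroup (for `Y`).
#'
#' @inheritParams convergence_experiment_backward
#' @param start diffusion start `(x, y)`.
#' @param dt_factor the step size at migration rate `c` is
#'   `dt_factor * c`, shrinking alongside `c` to keep the bias on the
#'   rescaled clock controlled.
#' @param seed integer seed.
#' @return A `"convergence_report"` whose `metric` is the `X`-moment gap;
#'   the `Y` gap and the raw moments are attached as fields.
#' @export
convergence_experiment_forward <- function(start, K, schedule, t, reps,
                                           dt_factor = 1e-3, seed = 1) {
  stopifnot(inherits(schedule, "scaling_schedule"))
  tc <- telegraph_closed_form(K, t)
  ex_x <- start[1] * tc$p11 + start[2] * tc$p10
  aalp <- build_aalp(sample_config(1, 1), K)
  ex_y <- limit_dual_moment_exact(aalp, 0, 1, start[1], start[2], t)
  est_x <- numeric(length(schedule$c_seq))
  est_y <- numeric(length(schedule$c_seq))
  se_x <- numeric(length(schedule$c_seq))
  mid_frac <- numeric(length(schedule$c_seq))
  for (i in seq_along(schedule$c_seq)) {
    cc <- schedule$c_seq[i]
    g <- rescale_super_evolutionary(start, cc, K, t_grid = t,
                                    dt = dt_factor * cc, reps = reps,
                                    seed = seed + i * 1e6)  # disjoint streams
    est_x[i] <- mean(g$x[, 1])
    est_y[i] <- mean(g$y[, 1])
    se_x[i] <- stats::sd(g$x[, 1]) / sqrt(reps)
    mid_frac[i] <- mean(g$x[, 1] > 0.05 & g$x[, 1] < 0.95)
  }
  out <- new_convergence_report(schedule$c_seq, abs(est_x - ex_x),
                                noise_floor = max(se_x))
  out$gap_y <- abs(est_y - ex_y)
  out$estimate_x <- est_x
  out$estimate_y <- est_y
  out$exact_x <- ex_x
  out$exact_y <- ex_y
  out$interior_fraction <- mid_frac
  out
}

new_convergence_report <- function(c_values, metric, noise_floor) {
  ord <- order(c_values, decreasing = TRUE)
  monotone <- all(diff(metric[ord]) <= 2 * noise_floor) &&
    sum(diff(metric[ord]) > 0) <= 1
  structure(list(c_values = c_values, metric = metric,
                 noise_floor = noise_floor, monotone = monotone,
                 final = metric[ord[length(ord)]]),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence_report\n")
  print(data.frame(c = x$c_values, metric = x$metric))
  cat(sprintf("monotone (<= 1 inversion within 2 x noise floor %.3g): %s; final %.4g\n",
              x$noise_floor, x$monotone, x$final))
  invisible(x)
}
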