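## Forward-in-time frequency diffusions: the seed bank diffusion and the
## two-island diffusion, simulated by Euler-Maruyama (compiled kernel), with
## the super-evolutionary time rescaling.

#' Euler-Maruyama configuration
#'
#' @param dt positive step size (time units of the simulated process).
#' @param horizon total simulated time; defaults to the largest record
#'   time.
#' @param reps number of independent replicates, at least 1.
#' @param seed integer seed; a single seed determines every draw (each
#'   replicate uses the sub-stream `seed + replicate`).
#' @param record_times times at which the state is recorded, within
#'   `[0, horizon]`.
#' @return An object of class `"em_config"`.
#' @export
em_config <- function(dt = 1e-3, horizon = max(record_times), reps = 1L,
                      seed = 1L, record_times = horizon) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(horizon), length(horizon) == 1L, horizon >= 0,
            is.numeric(reps), length(reps) == 1L, reps >= 1,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(record_times), length(record_times) >= 1)
  if (any(record_times < 0) || any(record_times > horizon + 1e-12))
    stop("'record_times' must lie within [0, horizon]")
  structure(list(dt = dt, horizon = horizon, reps = as.integer(reps),
                 seed = seed, record_times = sort(record_times)),
            class = "em_config")
}

new_path_grid <- function(times, x, y, model) {
  structure(list(times = times, x = x, y = y, model = model),
            class = "path_grid")
}

#' @export
print.path_grid <- function(x, ...) {
  cat(sprintf("path_grid (%s): %d replicates at %d record times in [%g, %g]\n",
              x$model, nrow(x$x), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

sim_twoisland_core <- function(start, c, K, alpha, alpha_prime, cfg, model) {
  stopifnot(inherits(cfg, "em_config"),
            is.numeric(start), length(start) == 2L,
            all(start >= 0), all(start <= 1))
  if (cfg$dt >= 1 / (c * (1 + K)))
    stop(sprintf(paste0("dt = %g risks drift overshoot: require ",
                        "dt < 1/(c*(1+K)) = %g"), cfg$dt, 1 / (c * (1 + K))))
  record_steps <- as.integer(round(cfg$record_times / cfg$dt))
  sim <- cpp_sim_twoisland(start[1], start[2], c, K, alpha, alpha_prime,
                           cfg$dt, record_steps, cfg$reps, cfg$seed)
  new_path_grid(record_steps * cfg$dt, sim$x, sim$y, model)
}

#' Simulate the seed bank diffusion
#'
#' Euler-Maruyama simulation of
#' `dX = c (Y - X) dt + sqrt(X (1 - X)) dB`,
#' `dY = K c (X - Y) dt`:
#' the allele frequency `X` in the active population feels genetic drift
#' and migration from the dormant pool, while the dormant frequency `Y`
#' relaxes deterministically towards `X`.  Interior steps use the plain
#' Gaussian Euler-Maruyama increment; within four standard deviations of a
#' boundary the increment is replaced by a two-point distribution with the
#' same conditional mean and variance supported inside `[0, 1]`, which
#' preserves the martingale structure that sets fixation probabilities
#' (truncating-and-clamping instead leaves a boundary-layer bias that does
#' not vanish with the step size).  The corners `(0, 0)` and `(1, 1)` are
#' exactly absorbing.  Record times are rounded to the nearest step.
#'
#' @param start numeric length-2 vector `(x0, y0)` in `[0, 1]^2`.
#' @param params a [model_params()]; `c` and `K` are used.
#' @param cfg an [em_config()].
#' @return A `"path_grid"`: list with `times` and `reps x length(times)`
#'   matrices `x`, `y`.
#' @examples
#' cfg <- em_config(dt = 1e-3, reps = 100, seed = 7, record_times = 1)
#' g <- simulate_seedbank_sde(c(0.3, 0.7), model_params(1, 2), cfg)
#' mean(2 * g$x + g$y)  # close to 2 * 0.3 + 0.7 (conserved in expectation)
#' @export
simulate_seedbank_sde <- function(start, params, cfg) {
  stopifnot(inherits(params, "model_params"))
  sim_twoisland_core(start, params$c, params$K, alpha = 1, alpha_prime = 0,
                     cfg, "seed bank diffusion")
}

#' Simulate the two-island diffusion
#'
#' As [simulate_seedbank_sde()] but with reproduction on both islands and
#' independent noise per coordinate:
#' `dX = c (Y - X) dt + alpha sqrt(X (1 - X)) dB`,
#' `dY = c K (X - Y) dt + alpha' sqrt(Y (1 - Y)) dB'`.
#' With `alpha = 1`, `alpha_prime = 0` it reproduces the seed bank
#' diffusion path for path under the same seed.
#'
#' @inheritParams simulate_seedbank_sde
#' @return A `"path_grid"`.
#' @export
simulate_twoisland_sde <- function(start, params, cfg) {
  stopifnot(inherits(params, "model_params"))
  sim_twoisland_core(start, params$c, params$K, params$alpha,
                     params$alpha_prime, cfg, "two-island diffusion")
}

#' Observe a diffusion on the super-evolutionary timescale
#'
#' Simulates the seed bank (or two-island) diffusion with migration rate
#' `c` on the stretched horizon `max(t_grid) / c` and reports the states at
#' the times `t / c`, i.e. observations of `(X^c(t / c), Y^c(t / c))` for
#' `t` in `t_grid`.  As `c` decreases these marginals approach the
#' jump-process limit; the step size should shrink along with `c` so the
#' per-unit-rescaled-time discretisation bias stays controlled (a warning
#' is issued when `dt > c * 1e-2`).
#'
#' @param start numeric length-2 vector in `[0, 1]^2`.
#' @param c migration rate of the prelimit diffusion.
#' @param K size ratio.
#' @param t_grid observation times on the rescaled clock.
#' @param dt step size on the original clock; default `c * 1e-3`.
#' @param reps replicates.
#' @param seed integer seed.
#' @param alpha,alpha_prime island coalescence scales; the defaults give
#'   the seed bank diffusion.
#' @return A `"path_grid"` whose `times` are the rescaled `t_grid`.
#' @export
rescale_super_evolutionary <- function(start, c, K, t_grid, dt = c * 1e-3,
                                       reps = 1L, seed = 1L,
                                       alpha = 1, alpha_prime = 0) {
  stopifnot(all(t_grid >= 0), c > 0)
  if (dt > c * 1e-2)
    warning("dt is not reduced alongside c; discretisation bias on the ",
            "rescaled clock grows like dt / c")
  cfg <- em_config(dt = dt, horizon = max(t_grid) / c, reps = reps,
                   seed = seed, record_times = t_grid / c)
  g <- sim_twoisland_core(start, c, K, alpha, alpha_prime, cfg,
                          sprintf("super-evolutionary rescaling, c = %g", c))
  g$times <- g$times * c
  g
}
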