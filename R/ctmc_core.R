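## Finite-state continuous-time Markov chains: rate matrices for the seed
## bank and structured coalescent block-counting processes, exact transition
## semigroups via the matrix exponential, and a generic jump-chain simulator.

new_rate_matrix <- function(entries, ss, model) {
  dimnames(entries) <- list(ss$labels, ss$labels)
  structure(entries, class = c("rate_matrix", "matrix", "array"),
            state_space = ss, model = model)
}

#' @export
print.rate_matrix <- function(x, ...) {
  ss <- attr(x, "state_space")
  cat(sprintf("rate_matrix (%s) on {0,...,%d}^2: %d x %d, max exit rate %g\n",
              attr(x, "model"), ss$nmax, nrow(x), ncol(x), max(-diag(x))))
  invisible(x)
}

#' Rate matrix of the seed bank coalescent block-counting process
#'
#' Builds the conservative Q-matrix of the continuous-time Markov chain
#' `(N(t), M(t))` counting active and dormant ancestral lineages of the seed
#' bank coalescent.  From state `(n, m)` the chain jumps to
#' `(n - 1, m)` at rate `choose(n, 2)` (coalescence of two active lineages),
#' to `(n - 1, m + 1)` at rate `c * n` (an active lineage becomes dormant),
#' and to `(n + 1, m - 1)` at rate `c * K * m` (a dormant lineage
#' resuscitates).  Dormant lineages never coalesce.  Transitions whose target
#' falls outside the enumerated grid are dropped; the diagonal is the
#' negative off-diagonal row sum, so every row sums to zero.
#'
#' @param sample a [sample_config()]; the state space is the grid
#'   `{0, ..., n0 + m0}^2`.
#' @param params a [model_params()]; only `c` and `K` are used.
#' @return A `"rate_matrix"`: a square matrix over [state_space()] with the
#'   state space attached as an attribute.
#' @examples
#' Q <- build_blockcounting_Q(sample_config(2, 0), model_params(c = 1, K = 1))
#' Q["(2,0)", "(1,0)"]  # coalescence at rate choose(2, 2) = 1
#' @seealso [build_structured_Q()] for the two-island variant,
#'   [transition_matrix()] for the exact semigroup.
#' @export
build_blockcounting_Q <- function(sample, params) {
  stopifnot(inherits(sample, "sample_config"), inherits(params, "model_params"))
  build_structured_Q(sample, model_params(params$c, params$K,
                                          alpha = 1, alpha_prime = 0))
}

#' Rate matrix of the structured (two-island) coalescent block-counting process
#'
#' Like [build_blockcounting_Q()] but with island-wise coalescence scales:
#' from `(n, m)` the chain jumps to `(n - 1, m)` at rate
#' `alpha * choose(n, 2)`, to `(n, m - 1)` at rate
#' `alpha_prime * choose(m, 2)` (coalescence on the second island), to
#' `(n - 1, m + 1)` at rate `c * n` and to `(n + 1, m - 1)` at rate
#' `c * K * m`.  `alpha_prime = 0` recovers the seed bank chain with
#' `alpha = 1` exactly.
#'
#' @inheritParams build_blockcounting_Q
#' @return A `"rate_matrix"`.
#' @export
build_structured_Q <- function(sample, params) {
  stopifnot(inherits(sample, "sample_config"), inherits(params, "model_params"))
  ss <- state_space(sample)
  S <- ss$size
  Q <- matrix(0, S, S)
  n <- ss$states$n
  m <- ss$states$m
  put <- function(from, n2, m2, rate) {
    ok <- rate > 0 & n2 >= 0 & m2 >= 0 & n2 <= ss$nmax & m2 <= ss$nmax
    idx <- cbind(from[ok], state_index(ss, n2[ok], m2[ok]))
    Q[idx] <<- Q[idx] + rate[ok]
  }
  from <- seq_len(S)
  put(from, n - 1, m,     params$alpha * choose2(n))
  put(from, n,     m - 1, params$alpha_prime * choose2(m))
  put(from, n - 1, m + 1, params$c * n)
  put(from, n + 1, m - 1, params$c * params$K * m)
  diag(Q) <- -rowSums(Q)
  model <- if (params$alpha_prime == 0 && params$alpha == 1)
    "seed bank block counting" else "structured coalescent block counting"
  new_rate_matrix(Q, ss, model)
}

## dense matrix exponential (Ward's scaled Pade, via Matrix)
expm_mat <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

#' Exact transition matrix of a continuous-time Markov chain
#'
#' Computes `expm(t * Q)`, the exact time-`t` transition semigroup of the
#' chain with conservative rate matrix `Q`.  Rows are probability vectors up
#' to the accuracy of the scaled Pade matrix exponential (about `1e-13`).
#'
#' @param Q a square conservative rate matrix (e.g. a `"rate_matrix"`).
#' @param t a single non-negative time.
#' @return A stochastic matrix of the same dimension (dimnames preserved).
#' @examples
#' Q <- build_blockcounting_Q(sample_config(1, 1), model_params(1, 1))
#' rowSums(transition_matrix(Q, 2))  # all 1
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q) || inherits(Q, "rate_matrix"),
            is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("time 't' must be >= 0")
  P <- if (t == 0) diag(nrow(Q)) else expm_mat(t * unclass(Q))
  dimnames(P) <- dimnames(Q)
  P
}

## Precompute, per state, the positive off-diagonal rates and their targets.
## Exit rates are taken as the sum of off-diagonal rates (not -diag), so
## substochastic boundary rows of windowed generators are handled gracefully.
jump_tables <- function(Q) {
  Q <- unclass(Q)
  lapply(seq_len(nrow(Q)), function(i) {
    r <- Q[i, ]
    r[i] <- 0
    j <- which(r > 0)
    list(targets = j, rates = r[j], total = sum(r[j]))
  })
}

#' Exact jump-chain (Gillespie) simulation of a finite-state CTMC
#'
#' Simulates one realisation of the continuous-time Markov chain with rate
#' matrix `Q`: holding times are exponential with the row's total
#' off-diagonal rate and the next state is chosen proportionally to the
#' off-diagonal rates.  The path is truncated at `horizon`; a state with
#' total rate zero absorbs the path.  Draws come from R's global RNG, so a
#' single `set.seed()` call makes the result reproducible.
#'
#' @param Q a `"rate_matrix"` (or plain conservative rate matrix).
#' @param start the starting state: either an index into the state space or,
#'   for a `"rate_matrix"`, a length-2 vector `c(n, m)`.
#' @param horizon non-negative time at which the path is truncated.
#' @param tables optional precomputed [jump tables][gillespie_simulate]
#'   (internal; reused across replicates for speed).
#' @return An object of class `"jump_path"`: a list with `times` (strictly
#'   increasing, starting at 0), `states` (matrix with columns `n`, `m`, one
#'   row per time; or a vector of indices for a plain matrix), and `horizon`.
#' @examples
#' Q <- build_blockcounting_Q(sample_config(2, 0), model_params(1, 1))
#' set.seed(1)
#' gillespie_simulate(Q, c(2, 0), horizon = 5)
#' @export
gillespie_simulate <- function(Q, start, horizon, tables = NULL) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 0)
  ss <- attr(Q, "state_space")
  i <- if (length(start) == 2L && !is.null(ss))
    state_index(ss, start[1], start[2]) else as.integer(start)
  stopifnot(i >= 1, i <= nrow(Q))
  if (is.null(tables)) tables <- jump_tables(Q)
  times <- 0
  path <- i
  t_now <- 0
  repeat {
    tab <- tables[[i]]
    if (tab$total <= 0) break                      # absorbing state
    t_now <- t_now + stats::rexp(1L, tab$total)
    if (t_now > horizon) break
    i <- if (length(tab$targets) == 1L) tab$targets else
      tab$targets[sample.int(length(tab$targets), 1L, prob = tab$rates)]
    times <- c(times, t_now)
    path <- c(path, i)
  }
  states <- if (!is.null(ss))
    cbind(n = ss$states$n[path], m = ss$states$m[path]) else path
  structure(list(times = times, states = states, horizon = horizon,
                 state_space = ss),
            class = "jump_path")
}

#' @export
print.jump_path <- function(x, ...) {
  cat(sprintf("jump_path: %d jumps on [0, %g]\n", length(x$times) - 1L,
              x$horizon))
  invisible(x)
}

#' Time-t marginal sample of a finite-state CTMC
#'
#' Draws `reps` independent realisations of the chain with rate matrix `Q`
#' started at `start` and returns the state occupied at time `t`.  Used by
#' the convergence experiments, where only the marginal law matters and
#' storing full paths would be wasteful.
#'
#' @inheritParams gillespie_simulate
#' @param t the observation time.
#' @param reps number of independent replicates.
#' @return An integer vector of length `reps` of state indices (see
#'   [state_index()]).
#' @export
simulate_ctmc_marginal <- function(Q, start, t, reps) {
  stopifnot(t >= 0, reps >= 1)
  ss <- attr(Q, "state_space")
  i0 <- if (length(start) == 2L && !is.null(ss))
    state_index(ss, start[1], start[2]) else as.integer(start)
  tables <- jump_tables(Q)
  out <- integer(reps)
  for (r in seq_len(reps)) {
    i <- i0
    t_now <- 0
    repeat {
      tab <- tables[[i]]
      if (tab$total <= 0) break
      t_now <- t_now + stats::rexp(1L, tab$total)
      if (t_now > t) break
      i <- if (length(tab$targets) == 1L) tab$targets else
        tab$targets[sample.int(length(tab$targets), 1L, prob = tab$rates)]
    }
    out[r] <- i
  }
  out
}

#' Total-variation distance between an empirical law and an exact row
#'
#' @param counts integer vector of state counts (e.g. tabulated output of
#'   [simulate_ctmc_marginal()]), one entry per state.
#' @param prob exact probability vector on the same state enumeration.
#' @return `0.5 * sum(abs(counts / sum(counts) - prob))`.
#' @export
tv_distance <- function(counts, prob) {
  stopifnot(length(counts) == length(prob))
  0.5 * sum(abs(counts / sum(counts) - prob))
}
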