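## Exact constructions of the limit genealogy in the super-evolutionary
## regime: the ancient ancestral lines process (degenerate semigroup
## P exp(tG) on the full grid), its reduced-state-space Q-matrix chain on
## {0,1} x {0,...,m_max}, the imbalanced two-island variant, the two-state
## telegraph closed form, and the restriction identity linking them.

#' The ancient ancestral lines process
#'
#' Constructs the limit genealogy of the strong seed bank model on the
#' super-evolutionary timescale: coalescence acts instantaneously, so for
#' every positive time there is at most one active lineage.  The process is
#' specified by a projection `P` (all states with `n >= 1` collapse to
#' `(1, m)`; states with `n = 0` are fixed) and a matrix `G` with entries
#' `K * m` into `(1, m - 1)` (resuscitation with immediate coalescence),
#' `1` into `(0, m + 1)` for `n >= 1` (initiation of dormancy),
#' `-1 - K * m` at column `(1, m)` for rows with `n >= 1` and `-K * m` on
#' the diagonal of `n = 0` rows.  `G` is not a rate matrix -- it has
#' negative entries off the diagonal in rows that `P` collapses -- and is
#' only ever used inside a matrix exponential; the semigroup is the
#' degenerate `Pi(t) = P exp(tG)` with `Pi(0)` the identity.
#'
#' @param sample a [sample_config()]; the state space is
#'   `{0, ..., n0 + m0}^2`.
#' @param K size ratio of active to dormant population, positive.
#' @return An object of class `"aalp"`: list with `P`, `G`, the
#'   [state_space()] `ss`, `K` and `sample`.
#' @examples
#' a <- build_aalp(sample_config(3, 2), K = 1)
#' a$P["(3,2)", "(1,2)"]   # 1: three active lines collapse to one
#' a$G["(2,1)", "(1,1)"]   # -1 - K: a negative off-diagonal entry
#' @seealso [aalp_semigroup()], [build_reduced_chain()],
#'   [restriction_identity_check()].
#' @export
build_aalp <- function(sample, K) {
  build_limit_pair(sample, K, island2_coal = FALSE)
}

#' The imbalanced two-island limit genealogy
#'
#' Variant of [build_aalp()] for the two-island model in which the island-2
#' coalescence scale decays like the migration rate: island-1 coalescence is
#' instantaneous (same projection `P`), while island 2 keeps ordinary
#' migration and coalescence.  The matrix `G` gains the island-2 coalescence
#' terms: rate `K * m + choose(m, 2)` into `(1, m - 1)` for rows with
#' `n >= 1` (resuscitation or island-2 coalescence, both reducing the
#' dormant count), `choose(m, 2)` into `(0, m - 1)` for `n = 0`, with
#' diagonals adjusted accordingly.
#'
#' @inheritParams build_aalp
#' @return An object of class `"aalp"` (with `model = "two-island"`).
#' @export
build_imbalanced_limit <- function(sample, K) {
  build_limit_pair(sample, K, island2_coal = TRUE)
}

build_limit_pair <- function(sample, K, island2_coal) {
  stopifnot(inherits(sample, "sample_config"),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (K <= 0) stop("size ratio 'K' must be > 0")
  ss <- state_space(sample)
  S <- ss$size
  n <- ss$states$n
  m <- ss$states$m

  P <- matrix(0, S, S, dimnames = list(ss$labels, ss$labels))
  tgt_n <- ifelse(n >= 1, 1L, 0L)
  P[cbind(seq_len(S), state_index(ss, tgt_n, m))] <- 1

  G <- matrix(0, S, S, dimnames = list(ss$labels, ss$labels))
  add <- function(n2, m2, val) {
    ok <- val != 0 & n2 >= 0 & m2 >= 0 & n2 <= ss$nmax & m2 <= ss$nmax
    idx <- cbind(which(ok), state_index(ss, n2[ok], m2[ok]))
    G[idx] <<- G[idx] + val[ok]
  }
  if (!island2_coal) {
    add(rep(1L, S), m - 1, K * m)                       # resuscitation, all n
    add(rep(0L, S), m + 1, as.numeric(n >= 1))          # dormancy, n >= 1
    add(rep(1L, S), m, ifelse(n >= 1, -1 - K * m, 0))   # column (1, m)
    add(rep(0L, S), m, ifelse(n == 0, -K * m, 0))       # diagonal, n = 0
  } else {
    add(rep(1L, S), m - 1, ifelse(n >= 1, K * m + choose2(m), K * m))
    add(rep(0L, S), m - 1, ifelse(n == 0, choose2(m), 0))
    add(rep(0L, S), m + 1, as.numeric(n >= 1))
    add(rep(1L, S), m, ifelse(n >= 1, -choose2(m) - 1 - K * m, 0))
    add(rep(0L, S), m, ifelse(n == 0, -choose2(m) - K * m, 0))
  }
  structure(list(P = P, G = G, ss = ss, K = K, sample = sample,
                 model = if (island2_coal) "two-island" else "seed bank"),
            class = "aalp")
}

#' @export
print.aalp <- function(x, ...) {
  cat(sprintf(
    "ancient ancestral lines process (%s): (n0,m0) = (%d,%d), K = %g\n",
    x$model, x$sample$n0, x$sample$m0, x$K))
  invisible(x)
}

#' Evaluate the degenerate semigroup of a limit genealogy
#'
#' `Pi(t) = P exp(tG)` for `t > 0` and the identity at `t = 0`.  For every
#' `t > 0` the rows supported on the reduced space `{0,1} x {0,...,m0+1}`
#' are probability vectors; rows `(n >= 1, m = n0 + m0)` of the enumeration
#' grid lose the out-of-grid dormancy move and are substochastic, but carry
#' no mass from any reachable start.
#'
#' @param aalp an `"aalp"` from [build_aalp()] or
#'   [build_imbalanced_limit()].
#' @param t single non-negative time.
#' @return A matrix over the full grid.
#' @export
aalp_semigroup <- function(aalp, t) {
  stopifnot(inherits(aalp, "aalp"))
  degenerate_semigroup(aalp$P, aalp$G, t)
}

#' Reduced-state-space limit chain
#'
#' The limit genealogy restricted to its effective state space
#' `{0, 1} x {0, ..., m_max}`: a Markov chain with Q-matrix entries
#' `K * m` into `(1, m - 1)` for `n` in `{0, 1}` (resuscitation, coalescing
#' immediately with the active line if one exists), `1` into `(0, m + 1)`
#' for `n = 1` (the active line goes dormant) and diagonal `-n - K * m`.
#' The dormancy move out of `(1, m_max)` falls outside the cap and is
#' dropped while the diagonal keeps its `-1 - K * m_max` value, exactly
#' mirroring how the full-grid matrix `G` truncates at the edge of its
#' enumeration; with the default cap `m_max = m0 + 1` that row is
#' unreachable from the canonical starts `(1, m0)` and `(0, m0)`, so every
#' reachable row is conservative.
#'
#' @param m_max dormant-count cap, at least 1.  Defaults in the examples
#'   and experiments to `m0 + 1`, the support bound of the limit process.
#' @param K size ratio, positive.
#' @return An object of class `"reduced_chain"`: list with the Q-matrix
#'   `Gbar`, `states` (data frame over `{0,1} x {0,...,m_max}`), `labels`,
#'   `m_max`, `K`.
#' @examples
#' rc <- build_reduced_chain(3, K = 1)
#' rc$Gbar["(1,2)", "(0,3)"]  # 1
#' rc$Gbar["(0,2)", "(1,1)"]  # 2 K
#' @export
build_reduced_chain <- function(m_max, K) {
  stopifnot(is.numeric(m_max), length(m_max) == 1L, m_max == round(m_max))
  if (m_max < 1) stop("'m_max' must be >= 1")
  if (K <= 0) stop("size ratio 'K' must be > 0")
  states <- expand.grid(m = 0:m_max, n = 0:1)[, c("n", "m")]
  rownames(states) <- NULL
  labels <- sprintf("(%d,%d)", states$n, states$m)
  S <- nrow(states)
  idx <- function(n, m) n * (m_max + 1L) + m + 1L
  Gbar <- matrix(0, S, S, dimnames = list(labels, labels))
  for (i in seq_len(S)) {
    n <- states$n[i]
    m <- states$m[i]
    if (m >= 1) Gbar[i, idx(1, m - 1)] <- K * m
    if (n == 1 && m + 1 <= m_max) Gbar[i, idx(0, m + 1)] <- 1
    Gbar[i, i] <- Gbar[i, i] - n - K * m
  }
  structure(list(Gbar = Gbar, states = states, labels = labels,
                 m_max = as.integer(m_max), K = K),
            class = "reduced_chain")
}

#' @export
print.reduced_chain <- function(x, ...) {
  cat(sprintf("reduced limit chain on {0,1} x {0,...,%d}, K = %g\n",
              x$m_max, x$K))
  invisible(x)
}

#' Restriction identity between the full and the reduced limit chain
#'
#' The semigroup `P exp(tG)` of the full-grid limit genealogy, restricted to
#' rows and columns in `{0, 1} x {0, ..., m_max}`, coincides with
#' `exp(t * Gbar)` of the reduced chain.  Both sides are computed by
#' independent matrix exponentials (of `G` and of `Gbar`, different
#' matrices of different dimension) and compared entrywise on the common
#' index set.
#'
#' @param aalp an `"aalp"` (seed bank variant).
#' @param reduced a `"reduced_chain"` with the same `K`.
#' @param t_grid vector of non-negative times.
#' @return List with `max_dev` (maximum absolute entry difference over the
#'   grid) and `dev_by_t`.
#' @export
restriction_identity_check <- function(aalp, reduced, t_grid) {
  stopifnot(inherits(aalp, "aalp"), inherits(reduced, "reduced_chain"))
  if (!isTRUE(all.equal(aalp$K, reduced$K)))
    stop("'aalp' and 'reduced' disagree on K")
  m_win <- min(reduced$m_max, aalp$ss$nmax)
  keep_full <- which(aalp$ss$states$n <= 1 & aalp$ss$states$m <= m_win)
  keep_red <- which(reduced$states$m <= m_win)
  dev_by_t <- vapply(t_grid, function(t) {
    lhs <- aalp_semigroup(aalp, t)[keep_full, keep_full, drop = FALSE]
    rhs <- if (t == 0) diag(length(keep_red)) else
      expm_mat(t * reduced$Gbar)[keep_red, keep_red, drop = FALSE]
    max(abs(lhs - unname(rhs)))
  }, numeric(1))
  list(max_dev = max(dev_by_t), dev_by_t = dev_by_t, t_grid = t_grid)
}

#' Closed-form transition probabilities of the single-line telegraph chain
#'
#' With exactly one ancestral line left, the limit genealogy reduces to the
#' two-state chain active `(1,0)` / dormant `(0,1)` with switching rates 1
#' (dormancy) and `K` (resuscitation).  Its transition probabilities are
#' `p11(t) = (K + exp(-(1 + K) t)) / (1 + K)` and `p10(t) = 1 - p11(t)`
#' (probabilities of the line being active or dormant at time `t` given it
#' started active).  All starts with `n >= 1`, `m = 0` share these laws for
#' `t > 0`.
#'
#' @param K size ratio, positive.
#' @param t vector of non-negative times.
#' @return A data frame with columns `t`, `p11`, `p10`.
#' @examples
#' telegraph_closed_form(1, c(0, 1, Inf))  # p11: 1, then -> K/(1+K)
#' @export
telegraph_closed_form <- function(K, t) {
  stopifnot(K > 0, all(t >= 0))
  p11 <- (K + exp(-(1 + K) * t)) / (1 + K)
  data.frame(t = t, p11 = p11, p10 = 1 - p11)
}

#' Simulate the limit genealogy via its reduced chain
#'
#' The matrix `G` of the full-grid limit genealogy has negative off-diagonal
#' entries, so its states cannot be simulated by exponential clocks.
#' Instead the process is realised exactly through the reduced chain: the
#' initial projection sends `(n0, m0)` with `n0 >= 1` to `(1, m0)` at time
#' `0+` (recorded as a jump at time 0), after which the reduced chain's
#' genuine Q-matrix drives the path.
#'
#' @param sample a [sample_config()].
#' @param K size ratio.
#' @param t observation time.
#' @param reps number of replicates.
#' @param m_max dormant-count cap; default `m0 + 1`.
#' @return List with `states` (integer matrix `reps x 2` of `(n, m)` at
#'   time `t`), the `"reduced_chain"` used, and the index vector into its
#'   enumeration.
#' @export
simulate_aalp_marginal <- function(sample, K, t, reps, m_max = sample$m0 + 1L) {
  stopifnot(inherits(sample, "sample_config"))
  rc <- build_reduced_chain(max(m_max, 1L), K)
  n_start <- min(sample$n0, 1L)
  i0 <- n_start * (rc$m_max + 1L) + sample$m0 + 1L
  Q <- rc$Gbar
  attr(Q, "state_space") <- NULL
  idx <- simulate_ctmc_marginal(Q, i0, t, reps)
  list(states = cbind(n = rc$states$n[idx], m = rc$states$m[idx]),
       reduced = rc, index = idx)
}
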