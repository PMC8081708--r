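## Generic separation-of-timescales engine for continuous-time Markov
## chains.  Discretise the chain on the intermediate scale 1/a, split the
## one-step transition matrix into a fast stochastic part A and a slow part
## B/b, extract the projection P = lim A^r, form the limit generator
## G = lim P B P, and evaluate the degenerate semigroup Pi(t) = P exp(tG).

#' Scaling schedule for the super-evolutionary limit
#'
#' For a decreasing sequence of migration rates `c_seq`, derives the
#' discretisation scale `a = c^-2` and the speed-up `b = c^-3` used
#' throughout the limit machinery; the observation timescale is
#' `b / a = 1 / c`.
#'
#' @param c_seq strictly decreasing vector of positive migration rates.
#' @return An object of class `"scaling_schedule"`: a list with `c_seq`,
#'   `a_seq`, `b_seq`.
#' @examples
#' scaling_schedule(c(0.2, 0.1, 0.05))
#' @export
scaling_schedule <- function(c_seq) {
  stopifnot(is.numeric(c_seq), length(c_seq) >= 1, all(c_seq > 0))
  if (length(c_seq) > 1 && any(diff(c_seq) >= 0))
    stop("'c_seq' must be strictly decreasing")
  structure(list(c_seq = c_seq, a_seq = c_seq^-2, b_seq = c_seq^-3),
            class = "scaling_schedule")
}

#' Maximum absolute row-sum matrix norm
#'
#' The norm `max_i sum_j |A_ij|`.  For a stochastic matrix this equals 1;
#' for a difference of stochastic matrices it measures the worst row in
#' total-variation-like terms (values in `[0, 2]`).
#'
#' @param A a square matrix.
#' @return A non-negative number.
#' @export
matrix_norm <- function(A) {
  stopifnot(is.matrix(A) || inherits(A, "Matrix"), nrow(A) == ncol(A))
  max(rowSums(abs(as.matrix(A))))
}

#' One-step transition matrix of the chain observed every 1/a time units
#'
#' Computes `expm(Q / a)` exactly rather than through the first-order
#' probability expansion, which removes an uncontrolled error term from the
#' downstream decomposition; the expansion survives only as a test assertion
#' (entries agree up to the expansion's own remainder).
#'
#' @param Q conservative rate matrix.
#' @param a positive step scale; the chain is observed at times `i / a`.
#' @return A stochastic matrix.
#' @export
discretise <- function(Q, a) {
  stopifnot(is.numeric(a), length(a) == 1L)
  if (a <= 0) stop("step scale 'a' must be > 0")
  P <- expm_mat(unclass(Q) / a)
  dimnames(P) <- dimnames(Q)
  P
}

#' Fast/slow decomposition of a one-step transition matrix
#'
#' Splits a stochastic matrix `Pi` into `Pi = A + B / b` where `A` keeps the
#' transitions flagged as fast by `mask` (off-diagonal entries copied from
#' `Pi`, diagonal adjusted so `A` is stochastic) and `B = b * (Pi - A)`
#' carries everything else on the slow timescale `b`.
#'
#' @param Pi stochastic matrix (e.g. from [discretise()]).
#' @param mask square logical matrix flagging the fast transitions; the
#'   diagonal is implicitly fast.  See [seedbank_fast_mask()] for the preset
#'   used by the seed bank and two-island chains.
#' @param b positive timescale factor.
#' @return An object of class `"timescale_decomposition"`: list with `A`,
#'   `B`, `b`.
#' @export
decompose <- function(Pi, mask, b) {
  stopifnot(is.matrix(Pi), is.logical(mask), all(dim(mask) == dim(Pi)),
            is.numeric(b), length(b) == 1L, b > 0)
  A <- matrix(0, nrow(Pi), ncol(Pi), dimnames = dimnames(Pi))
  off <- mask
  diag(off) <- FALSE
  A[off] <- Pi[off]
  diag(A) <- 1 - rowSums(A)
  if (any(diag(A) < 0))
    stop("mask makes A non-stochastic (negative diagonal); ",
         "fast transitions carry too much mass")
  B <- b * (Pi - A)
  structure(list(A = A, B = B, b = b), class = "timescale_decomposition")
}

#' Fast-transition mask for the seed bank / two-island chains
#'
#' In the super-evolutionary regime coalescence among active lineages is the
#' fast event: the mask flags the moves `(n, m) -> (n - 1, m)` for
#' `n >= 2` (a single active lineage cannot coalesce, so the tiny
#' multi-jump mass that the exact discretisation places on
#' `(1, m) -> (0, m)` belongs to the slow part) and the diagonal, which is
#' always fast.
#'
#' @param ss a [state_space()].
#' @return A logical matrix of the same dimension as the chain's rate
#'   matrix.
#' @export
seedbank_fast_mask <- function(ss) {
  stopifnot(inherits(ss, "state_space"))
  M <- matrix(FALSE, ss$size, ss$size, dimnames = list(ss$labels, ss$labels))
  n <- ss$states$n
  m <- ss$states$m
  ok <- n >= 2
  M[cbind(which(ok), state_index(ss, n[ok] - 1, m[ok]))] <- TRUE
  diag(M) <- TRUE
  M
}

#' Numerical extraction of the projection P = lim A^r
#'
#' Raises the fast matrix `A` to the powers `ceiling(C * a)` over a grid
#' of constants `C` (by binary exponentiation), snaps the entries of the
#' largest power to `{0, 1}` when within `snap_tol`, and verifies that the
#' result is an idempotent stochastic matrix.  The norm decay sequence
#' `||A^r - P||` is returned as a diagnostic; the double limit over `C` and
#' the schedule can only ever be sampled on a finite grid, so this is a
#' finite-grid surrogate for the limiting statement.
#'
#' @param A stochastic matrix of fast transitions.
#' @param a discretisation scale (so `r` of order `C * a` steps correspond
#'   to order-`C` units of pre-limit time).
#' @param C_grid increasing vector of positive constants.
#' @param snap_tol entries of the candidate limit within this distance of 0
#'   or 1 are snapped; far above accumulated floating-point error and far
#'   below the smallest genuine transition probability of interest.
#' @return List with `P` (the projection), `C_grid`, `r_grid`,
#'   `norm_decay` (`||A^r - P||` per `C`) and `idempotency_dev`
#'   (`max |P^2 - P|`).
#' @export
extract_projection <- function(A, a, C_grid = c(1, 10, 100),
                               snap_tol = 1e-6) {
  stopifnot(is.matrix(A), a > 0, all(C_grid > 0), !is.unsorted(C_grid))
  r_grid <- as.integer(ceiling(C_grid * a))
  powers <- lapply(r_grid, function(r) mat_power(A, r))
  P <- powers[[length(powers)]]
  snap <- abs(P) < snap_tol | abs(P - 1) < snap_tol
  if (!all(snap))
    stop("no stabilisation detected: A^r has entries away from {0,1} ",
         "at the largest C (max interior entry ",
         format(max(pmin(abs(P), abs(P - 1))[!snap])), ")")
  P <- round(P)
  norm_decay <- vapply(powers, function(M) matrix_norm(M - P), numeric(1))
  if (norm_decay[length(norm_decay)] > 0.1)
    stop("no stabilisation detected: ||A^r - P|| = ",
         format(norm_decay[length(norm_decay)]), " at the largest C")
  list(P = P, C_grid = C_grid, r_grid = r_grid, norm_decay = norm_decay,
       idempotency_dev = max(abs(P %*% P - P)))
}

## matrix power by binary exponentiation
mat_power <- function(A, r) {
  stopifnot(r >= 0)
  out <- diag(nrow(A))
  dimnames(out) <- dimnames(A)
  base <- A
  while (r > 0) {
    if (r %% 2 == 1) out <- out %*% base
    base <- base %*% base
    r <- r %/% 2
  }
  out
}

#' Limit generator G = lim P B P
#'
#' Given the projection `P` and the slow matrices `B` along a schedule,
#' computes the sequence `P B P` and checks it for stabilisation by a Cauchy
#' criterion in [matrix_norm()].  When the exact limit matrix `B_limit` is
#' supplied (the seed bank and two-island chains have closed forms, see
#' [seedbank_B_limit()]), the exact product `P B_limit P` is returned as
#' `G`; otherwise `G` is the last element of the sequence.
#'
#' @param P idempotent stochastic matrix.
#' @param B_seq list of slow matrices along the schedule (may be `NULL` when
#'   `B_limit` is given).
#' @param B_limit optional exact limit of the `B` sequence.
#' @param tol Cauchy tolerance on successive differences of `P B P`.
#' @return List with `G`, `G_seq`, `cauchy_gaps` and `converged`.
#' @export
limit_generator <- function(P, B_seq = NULL, B_limit = NULL, tol = 1e-8) {
  stopifnot(max(abs(P %*% P - P)) == 0)
  G_seq <- NULL
  gaps <- numeric(0)
  converged <- NA
  if (!is.null(B_seq)) {
    G_seq <- lapply(B_seq, function(B) P %*% B %*% P)
    if (length(G_seq) > 1)
      gaps <- vapply(seq_len(length(G_seq) - 1), function(i)
        matrix_norm(G_seq[[i + 1]] - G_seq[[i]]), numeric(1))
    converged <- length(gaps) > 0 && gaps[length(gaps)] < tol
  }
  if (!is.null(B_limit)) {
    G <- P %*% B_limit %*% P
  } else {
    if (is.null(G_seq)) stop("supply 'B_seq' and/or 'B_limit'")
    if (!isTRUE(converged))
      stop("P B P sequence is not Cauchy at tolerance ", tol,
           " (last gap ", format(gaps[length(gaps)]), ")")
    G <- G_seq[[length(G_seq)]]
  }
  list(G = G, G_seq = G_seq, cauchy_gaps = gaps, converged = converged)
}

#' Exact limit of the slow matrix for the seed bank chain
#'
#' Entrywise limit of the slow part `B` of the discretised seed bank
#' block-counting chain: rate `n` for initiation of dormancy
#' `(n, m) -> (n - 1, m + 1)`, rate `K m` for resuscitation
#' `(n, m) -> (n + 1, m - 1)`, diagonal `-n - K m`; targets outside the grid
#' are dropped.  `P %*% seedbank_B_limit(ss, K) %*% P` equals the limit
#' generator of the ancient ancestral lines process entrywise.
#'
#' @param ss a [state_space()].
#' @param K size ratio.
#' @return A square matrix over `ss`.
#' @export
seedbank_B_limit <- function(ss, K) {
  B_limit_build(ss, K, island2_coal = FALSE)
}

#' Exact limit of the slow matrix for the imbalanced two-island chain
#'
#' As [seedbank_B_limit()], plus island-2 coalescence `(n, m) -> (n, m - 1)`
#' at rate `choose(m, 2)` (the regime where the island-2 coalescence scale
#' decays like the migration rate), with the diagonal adjusted accordingly.
#'
#' @inheritParams seedbank_B_limit
#' @return A square matrix over `ss`.
#' @export
structured_B_limit <- function(ss, K) {
  B_limit_build(ss, K, island2_coal = TRUE)
}

B_limit_build <- function(ss, K, island2_coal) {
  stopifnot(inherits(ss, "state_space"), K > 0)
  S <- ss$size
  B <- matrix(0, S, S, dimnames = list(ss$labels, ss$labels))
  n <- ss$states$n
  m <- ss$states$m
  put <- function(n2, m2, rate) {
    ok <- rate > 0 & n2 >= 0 & m2 >= 0 & n2 <= ss$nmax & m2 <= ss$nmax
    B[cbind(which(ok), state_index(ss, n2[ok], m2[ok]))] <<- rate[ok]
  }
  put(n - 1, m + 1, n)
  put(n + 1, m - 1, K * m)
  dg <- -n - K * m
  if (island2_coal) {
    put(n, m - 1, choose2(m))
    dg <- dg - choose2(m)
  }
  diag(B) <- diag(B) + dg
  B
}

#' Degenerate transition semigroup Pi(t) = P exp(tG)
#'
#' Evaluates the non-standard semigroup of a separation-of-timescales limit:
#' the identity at `t = 0` and `P %*% expm(t * G)` for `t > 0`, so that
#' `Pi(0+) = P` differs from `Pi(0)` (the semigroup is not standard).
#' Requires `P` idempotent and `P G = G P = G`.
#'
#' @param P idempotent stochastic matrix.
#' @param G limit generator (may have negative off-diagonal entries; it is
#'   only ever used inside the matrix exponential).
#' @param t single non-negative time.
#' @return A matrix over the same state enumeration.
#' @export
degenerate_semigroup <- function(P, G, t) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("time 't' must be >= 0")
  if (max(abs(P %*% P - P)) > 1e-12) stop("'P' is not idempotent")
  if (max(abs(P %*% G - G)) > 1e-10 || max(abs(G %*% P - G)) > 1e-10)
    stop("'G' does not satisfy PG = GP = G")
  if (t == 0) {
    out <- diag(nrow(P))
    dimnames(out) <- dimnames(P)
    return(out)
  }
  out <- P %*% expm_mat(t * G)
  dimnames(out) <- dimnames(P)
  out
}

#' Check the first-jump condition for the discretisation scale
#'
#' For a sequence of rate matrices along a schedule, computes the maximal
#' exit rate `q = max_e (-Q_ee)` and the ratio `q / a`.  The discretisation
#' is fine enough for the limit to survive the passage back to continuous
#' time exactly when this ratio tends to zero; a constant ratio is flagged
#' as failing.
#'
#' @param Q_seq list of conservative rate matrices along the schedule.
#' @param a_seq vector of discretisation scales, same length.
#' @return List with `q_seq`, `ratio` and `ok` (`TRUE` iff the ratio is
#'   strictly decreasing and the last value is below the first).
#' @export
check_exit_rate_ratio <- function(Q_seq, a_seq) {
  stopifnot(is.list(Q_seq), length(Q_seq) == length(a_seq))
  q_seq <- vapply(Q_seq, function(Q) max(-diag(as.matrix(Q))), numeric(1))
  ratio <- q_seq / a_seq
  ok <- length(ratio) > 1 && all(diff(ratio) < 0)
  list(q_seq = q_seq, ratio = ratio, ok = ok)
}
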