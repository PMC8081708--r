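#' Model parameters for the seed bank and two-island models
#'
#' Bundles the rates that parameterise every process in the package: the
#' migration/switching rate `c` between the active and the dormant (or second
#' island) population, the ratio `K` of active to dormant population size,
#' and the island-wise coalescence scales `alpha` (island 1 / active) and
#' `alpha_prime` (island 2 / dormant).  The pure seed bank model is the
#' special case `alpha = 1`, `alpha_prime = 0`: no coalescence (i.e. no
#' reproduction) among dormant lineages.
#'
#' @param c migration/switching rate, a finite positive number.
#' @param K ratio of active to dormant population size, finite positive.
#' @param alpha coalescence scale in the active population, non-negative.
#' @param alpha_prime coalescence scale in the dormant population,
#'   non-negative.  `0` recovers the seed bank model.
#'
#' @return An object of class `"model_params"`: a list with components
#'   `c`, `K`, `alpha`, `alpha_prime`.
#' @examples
#' model_params(c = 0.1, K = 2)
#' @export
model_params <- function(c, K, alpha = 1, alpha_prime = 0) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(alpha_prime), length(alpha_prime) == 1L,
            is.finite(alpha_prime))
  if (c <= 0) stop("migration rate 'c' must be > 0")
  if (K <= 0) stop("size ratio 'K' must be > 0")
  if (alpha < 0 || alpha_prime < 0)
    stop("coalescence scales 'alpha' and 'alpha_prime' must be >= 0")
  structure(list(c = c, K = K, alpha = alpha, alpha_prime = alpha_prime),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: c = %g, K = %g, alpha = %g, alpha' = %g\n",
              x$c, x$K, x$alpha, x$alpha_prime))
  invisible(x)
}

#' Sample configuration for backward-in-time processes
#'
#' The initial number of active (`n0`) and dormant (`m0`) ancestral lineages
#' of a sample.  At least one lineage is required.
#'
#' @param n0 non-negative integer, initial active lineage count.
#' @param m0 non-negative integer, initial dormant lineage count.
#' @return An object of class `"sample_config"`.
#' @examples
#' sample_config(3, 2)
#' @export
sample_config <- function(n0, m0) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 == round(n0), n0 >= 0,
            is.numeric(m0), length(m0) == 1L, m0 == round(m0), m0 >= 0)
  if (n0 + m0 < 1) stop("sample must contain at least one lineage (n0 + m0 >= 1)")
  structure(list(n0 = as.integer(n0), m0 = as.integer(m0)),
            class = "sample_config")
}

#' @export
print.sample_config <- function(x, ...) {
  cat(sprintf("sample_config: n0 = %d active, m0 = %d dormant\n", x$n0, x$m0))
  invisible(x)
}

#' Enumerated state space for block-counting chains
#'
#' The full grid `{0, ..., n0 + m0}^2` of (active, dormant) lineage counts,
#' enumerated row-major in `n` then `m`: the state `(n, m)` sits at position
#' `n * (n0 + m0 + 1) + m + 1`.  The grid deliberately includes states that
#' are unreachable from `(n0, m0)` (total lineage count can only decrease);
#' the simple bijective indexing outweighs the wasted rows.
#'
#' @param sample a [sample_config()].
#' @return An object of class `"state_space"`: a list with `states`
#'   (data frame of `n`, `m`), `labels`, `size` and `nmax = n0 + m0`.
#' @examples
#' ss <- state_space(sample_config(2, 1))
#' ss$size   # (2 + 1 + 1)^2 = 16
#' @export
state_space <- function(sample) {
  stopifnot(inherits(sample, "sample_config"))
  nmax <- sample$n0 + sample$m0
  grid <- expand.grid(m = 0:nmax, n = 0:nmax)[, c("n", "m")]
  rownames(grid) <- NULL
  labels <- sprintf("(%d,%d)", grid$n, grid$m)
  structure(list(states = grid, labels = labels,
                 size = nrow(grid), nmax = nmax, sample = sample),
            class = "state_space")
}

#' Position of a state in a state space
#'
#' @param ss a [state_space()].
#' @param n,m integer coordinates of the state.
#' @return The row/column index of `(n, m)`, an integer in `1:ss$size`.
#' @examples
#' state_index(state_space(sample_config(2, 1)), 1, 0)
#' @export
state_index <- function(ss, n, m) {
  stopifnot(inherits(ss, "state_space"))
  if (any(n < 0) || any(m < 0) || any(n > ss$nmax) || any(m > ss$nmax))
    stop(sprintf("state (%s,%s) outside the grid {0,...,%d}^2",
                 n[1], m[1], ss$nmax))
  as.integer(n * (ss$nmax + 1L) + m + 1L)
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space on {0,...,%d}^2: %d states (row-major in n, then m)\n",
              x$nmax, x$size))
  invisible(x)
}

## binom(n, 2) with the convention choose2(n) = 0 for n <= 1
choose2 <- function(n) ifelse(n >= 2, n * (n - 1) / 2, 0)
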