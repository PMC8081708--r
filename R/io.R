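## Plain-text serialisation: rate matrices and semigroup objects to JSON,
## simulated paths to CSV.  All floats are written with 17 significant
## digits so round-trips are bit-faithful.

#' Serialise a matrix over a state space to JSON
#'
#' Writes the state list and the dense entries, so the file is
#' self-describing and [read_matrix_json()] can rebuild the labelled matrix.
#'
#' @param M a matrix (a `"rate_matrix"` or any matrix over a
#'   [state_space()]).
#' @param file path of the JSON file to write.
#' @param ss the state space; taken from `M`'s attributes if absent.
#' @return `file`, invisibly.
#' @export
write_matrix_json <- function(M, file, ss = attr(M, "state_space")) {
  stopifnot(!is.null(ss))
  obj <- list(n0 = ss$sample$n0, m0 = ss$sample$m0,
              states = ss$states,
              entries = unname(as.matrix(unclass(M))))
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(file)
}

#' Read a matrix written by [write_matrix_json()]
#'
#' @param file path of the JSON file.
#' @return The matrix with state labels as dimnames and the rebuilt state
#'   space attached as attribute `"state_space"`.
#' @export
read_matrix_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  ss <- state_space(sample_config(obj$n0, obj$m0))
  M <- obj$entries
  stopifnot(is.matrix(M), nrow(M) == ss$size, ncol(M) == ss$size,
            identical(ss$states$n, as.integer(obj$states$n)),
            identical(ss$states$m, as.integer(obj$states$m)))
  dimnames(M) <- list(ss$labels, ss$labels)
  attr(M, "state_space") <- ss
  M
}

#' Write jump paths to CSV
#'
#' One row per visited state, columns `replicate`, `time`, `n`, `m`.
#'
#' @param paths a `"jump_path"` or a list of them.
#' @param file path of the CSV file.
#' @return `file`, invisibly.
#' @export
write_jump_paths_csv <- function(paths, file) {
  if (inherits(paths, "jump_path")) paths <- list(paths)
  rows <- do.call(rbind, lapply(seq_along(paths), function(r) {
    p <- paths[[r]]
    data.frame(replicate = r, time = p$times,
               n = p$states[, "n"], m = p$states[, "m"])
  }))
  write_csv17(rows, file)
  invisible(file)
}

#' Write a diffusion/PDMP path grid to CSV
#'
#' One row per (replicate, time), columns `replicate`, `time`, `x`, `y`.
#'
#' @param grid a `"path_grid"` (see [simulate_seedbank_sde()]).
#' @param file path of the CSV file.
#' @return `file`, invisibly.
#' @export
write_path_grid_csv <- function(grid, file) {
  stopifnot(inherits(grid, "path_grid"))
  reps <- nrow(grid$x)
  rows <- data.frame(
    replicate = rep(seq_len(reps), times = length(grid$times)),
    time = rep(grid$times, each = reps),
    x = as.vector(grid$x), y = as.vector(grid$y))
  write_csv17(rows, file)
  invisible(file)
}

## data.frame to CSV with full double precision
write_csv17 <- function(df, file) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}
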