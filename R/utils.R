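# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed`, restoring the
#' previous RNG state afterwards.  A `NULL` seed leaves the RNG untouched,
#' so callers can opt into irreproducible behaviour explicitly.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

#' Upper-triangle index of a region pair
#'
#' Maps a region pair (i, j), i < j, to its position in the row-major
#' upper-triangle connectivity vector of an m-region correlation matrix,
#' i.e. the ordering (1,2), (1,3), ..., (1,m), (2,3), ...
#'
#' @param i,j 1-based region indices with `i < j`.
#' @param m total number of regions.
#' @return Integer position in `1..m*(m-1)/2`.  Vectorised over `i`, `j`.
#' @examples
#' pair_index(1, 2, 4)  # 1
#' pair_index(3, 4, 4)  # 6
#' @export
pair_index <- function(i, j, m) {
  stopifnot(all(i >= 1L), all(j > i), all(j <= m))
  as.integer((i - 1L) * (2L * m - i) / 2L + (j - i))
}

stop_fc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fcdiag_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
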