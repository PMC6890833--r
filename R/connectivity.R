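# Pearson functional connectivity and the extreme-correlation feature mask.
#
# Each subject's T x m ROI time series yields an m x m correlation matrix;
# its strictly upper triangle (row-major over pairs (i, j), i < j) is the
# connectivity vector of length q = m(m-1)/2.  The feature mask keeps the
# indices of the most positive and most negative *training-set average*
# correlations, so feature selection never sees held-out subjects.

#' Pairwise Pearson correlation matrix of an ROI time series
#'
#' Computes the m x m matrix of Pearson correlations between all region
#' pairs.  Zero-variance (constant) columns cannot be correlated; any pair
#' involving one is set to 0 by convention (neutral for extreme-value
#' masking) and a message is emitted.
#'
#' @param ts an `roi_ts` object or a numeric T x m matrix (T >= 2).
#' @return Symmetric m x m matrix with unit diagonal (for non-constant
#'   columns).
#' @export
pearson_matrix <- function(ts) {
  mat <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  if (nrow(mat) < 2L)
    stop_fc("need at least 2 timepoints to correlate (got %d)", nrow(mat),
            class = "fcdiag_insufficient_data_error")
  sds <- apply(mat, 2L, stats::sd)
  zv <- which(sds == 0)
  C <- suppressWarnings(stats::cor(mat))
  if (length(zv) > 0L) {
    message(sprintf("pearson_matrix: %d zero-variance column(s) (%s); their correlations set to 0",
                    length(zv), paste(utils::head(zv, 5L), collapse = ", ")))
    C[zv, ] <- 0
    C[, zv] <- 0
  }
  C
}

#' Vectorize the strictly upper triangle of a symmetric matrix
#'
#' Entries are ordered row-major over pairs (i, j) with i < j:
#' (1,2), (1,3), ..., (1,m), (2,3), ...; [pair_index()] maps a region pair
#' to its position.
#'
#' @param C symmetric m x m matrix.
#' @return Numeric vector of length m(m-1)/2 with attribute `m`.
#' @export
upper_triangle_vector <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C))
    stop_fc("matrix must be square (got %dx%d)", nrow(C), ncol(C),
            class = "fcdiag_shape_error")
  if (max(abs(C - t(C))) > 1e-8)
    stop_fc("matrix is not symmetric", class = "fcdiag_shape_error")
  v <- t(C)[lower.tri(C)]  # row-major over (i < j)
  attr(v, "m") <- nrow(C)
  v
}

#' Build the extreme-correlation feature mask from training subjects
#'
#' Averages the connectivity vectors element-wise over training subjects and
#' keeps the indices of the `floor(q * fraction)` largest and
#' `floor(q * fraction)` smallest averaged correlations (default one quarter
#' each, i.e. half of all q features).  Ties are broken by lower index; if
#' the two extremes would overlap (possible only on heavily tied input), the
#' smallest-value arm draws from the remaining indices so the mask size is
#' always exactly `2 * floor(q * fraction)`.
#'
#' @param training_vectors a list of connectivity vectors, or a numeric
#'   matrix with one row per training subject.
#' @param fraction fraction of features kept from each extreme (default
#'   0.25).
#' @return An object of class `feature_mask`: a list with sorted 1-based
#'   `indices`, the source length `q` and `fraction`.
#' @export
compute_mask <- function(training_vectors, fraction = 0.25) {
  V <- if (is.list(training_vectors)) {
    if (length(training_vectors) == 0L)
      stop_fc("need at least one training vector", class = "fcdiag_empty_error")
    if (length(unique(lengths(training_vectors))) != 1L)
      stop_fc("training vectors have mixed lengths", class = "fcdiag_shape_error")
    do.call(rbind, training_vectors)
  } else as.matrix(training_vectors)
  if (nrow(V) == 0L)
    stop_fc("need at least one training vector", class = "fcdiag_empty_error")
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 0.5)
    stop_fc("fraction must be in (0, 0.5]", class = "fcdiag_value_error")
  avg <- colMeans(V)
  q <- length(avg)
  n_side <- floor(q * fraction)
  if (n_side < 1L)
    stop_fc("q = %d too small for fraction %g", q, fraction,
            class = "fcdiag_value_error")
  top <- utils::head(order(-avg, seq_len(q)), n_side)
  rest <- setdiff(order(avg, seq_len(q)), top)
  bottom <- utils::head(rest, n_side)
  structure(list(indices = sort(c(top, bottom)), q = q, fraction = fraction),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d of %d features (fraction %g per extreme)\n",
              length(x$indices), x$q, x$fraction))
  invisible(x)
}

#' Restrict a connectivity vector to a feature mask
#'
#' @param v connectivity vector of length `mask$q`.
#' @param mask a `feature_mask` from [compute_mask()].
#' @return Numeric vector `v[mask$indices]` (index order preserved).
#' @export
apply_mask <- function(v, mask) {
  stopifnot(inherits(mask, "feature_mask"))
  if (length(v) != mask$q)
    stop_fc("vector length %d does not match mask source length %d",
            length(v), mask$q, class = "fcdiag_shape_error")
  as.numeric(v)[mask$indices]
}

#' Serialize / restore a feature mask as plain JSON
#'
#' The mask is stored as its 1-based index list plus `q` and `fraction`,
#' so a training-time mask can be reused at prediction time.
#'
#' @param mask a `feature_mask`.
#' @param path JSON file path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "feature_mask"))
  jsonlite::write_json(unclass(mask), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(indices = as.integer(x$indices), q = as.integer(x$q),
                 fraction = as.numeric(x$fraction)),
            class = "feature_mask")
}
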