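# Extended Frobenius Norm (EROS) similarity between multivariate time
# series.  Each subject is summarised by the leading eigenvalues and
# eigenvectors of its m x m region covariance matrix; the similarity of two
# subjects is a weighted sum of absolute cosines between rank-corresponding
# eigenvectors, with weights derived from the eigenvalue spectra of the
# training set.  Two components suffice in practice for kNN retrieval, so
# n defaults to 2.

#' Leading eigen-decomposition of a subject's region covariance
#'
#' Computes the sample covariance of the T x m series (columns centred,
#' divisor T - 1) and returns its `n` largest-eigenvalue components.
#' Eigenvector signs are canonicalized so the largest-magnitude entry of
#' each vector is positive, making summaries comparable across subjects.
#'
#' @param ts an `roi_ts` object or numeric T x m matrix.
#' @param n number of leading components to keep (default 2).
#' @return An object of class `eigen_summary`: `values` (length n,
#'   descending), `vectors` (m x n, orthonormal columns), `n`, `m`, and the
#'   subject's `subject_id`/`label` when available.
#' @export
covariance_eigen <- function(ts, n = 2L) {
  mat <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  m <- ncol(mat)
  if (nrow(mat) < 2L)
    stop_fc("need at least 2 timepoints (got %d)", nrow(mat),
            class = "fcdiag_insufficient_data_error")
  if (!is_scalar_number(n) || n < 1L || n > m)
    stop_fc("component count n must be in 1..%d (got %s)", m, n,
            class = "fcdiag_parameter_error")
  n <- as.integer(n)
  e <- eigen(stats::cov(mat), symmetric = TRUE)
  vecs <- e$vectors[, seq_len(n), drop = FALSE]
  for (k in seq_len(n)) {
    pivot <- which.max(abs(vecs[, k]))
    if (vecs[pivot, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(
    list(values = e$values[seq_len(n)], vectors = vecs, n = n, m = m,
         subject_id = if (inherits(ts, "roi_ts")) ts$subject_id else NA_character_,
         label = if (inherits(ts, "roi_ts")) ts$label else NA_integer_),
    class = "eigen_summary")
}

#' EROS weight vector from a training-set eigenvalue matrix
#'
#' Given the n x N matrix `S` whose column i holds the retained eigenvalues
#' of the i-th training subject: each column is normalized to sum 1, each
#' row is aggregated (default mean), and the aggregate vector is
#' renormalized so the weights sum exactly to 1.
#'
#' @param S n x N matrix of non-negative eigenvalues (columns = subjects),
#'   or a list of `eigen_summary` objects from which it is assembled.
#' @param aggregate aggregate function name: `"mean"` (default), `"min"` or
#'   `"max"`.
#' @return An object of class `eros_weights` with fields `w` (length n,
#'   non-negative, summing to 1) and `aggregate`.
#' @export
eros_weights <- function(S, aggregate = c("mean", "min", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.list(S) && all(vapply(S, inherits, logical(1), "eigen_summary")))
    S <- vapply(S, function(e) e$values, numeric(S[[1L]]$n))
  S <- as.matrix(S)
  if (ncol(S) < 1L)
    stop_fc("need at least one subject column", class = "fcdiag_empty_error")
  if (any(S < 0))
    stop_fc("eigenvalue matrix has negative entries", class = "fcdiag_domain_error")
  cs <- colSums(S)
  if (any(cs <= 0))
    stop_fc("subject %d has an all-zero eigenvalue column (degenerate item)",
            which(cs <= 0)[1L], class = "fcdiag_degenerate_error")
  Sn <- sweep(S, 2L, cs, "/")
  f <- switch(aggregate, mean = mean, min = min, max = max)
  w <- apply(Sn, 1L, f)
  w <- w / sum(w)
  structure(list(w = as.numeric(w), aggregate = aggregate),
            class = "eros_weights")
}

#' EROS similarity between two eigen summaries
#'
#' Returns `sum_i w_i * |<a_i, b_i>|`, the weighted absolute cosine between
#' rank-corresponding unit eigenvectors.  The score lies in \[0, 1\], equals
#' 1 for identical eigenvector sets, is symmetric in its arguments, and is
#' invariant to eigenvector sign flips.
#'
#' @param A,B `eigen_summary` objects with equal component count.
#' @param w an `eros_weights` object of matching length.
#' @return Similarity score in \[0, 1\].
#' @export
eros_similarity <- function(A, B, w) {
  stopifnot(inherits(A, "eigen_summary"), inherits(B, "eigen_summary"),
            inherits(w, "eros_weights"))
  if (A$n != B$n || A$n != length(w$w) || A$m != B$m)
    stop_fc("dimension mismatch: A has n=%d m=%d, B has n=%d m=%d, w has length %d",
            A$n, A$m, B$n, B$m, length(w$w), class = "fcdiag_shape_error")
  cosines <- pmin(abs(colSums(A$vectors * B$vectors)), 1)
  sum(w$w * cosines)
}

#' Pairwise EROS similarity matrix
#'
#' @param eigens list of `eigen_summary` objects.
#' @param w an `eros_weights` object.
#' @return Symmetric N x N matrix of similarities with unit diagonal.
#' @export
eros_similarity_matrix <- function(eigens, w) {
  N <- length(eigens)
  M <- diag(1, N)
  if (N > 1L)
    for (i in seq_len(N - 1L))
      for (j in seq(i + 1L, N)) {
        s <- eros_similarity(eigens[[i]], eigens[[j]], w)
        M[i, j] <- M[j, i] <- s
      }
  M
}

#' k nearest neighbours under EROS similarity
#'
#' Ranks `candidates` by EROS similarity to `target` (highest first, ties
#' broken by lower candidate index) and returns up to `k` of them,
#' restricted to the target's class when `same_class_only` is set.  If fewer
#' than `k` eligible candidates exist they are all returned with a warning.
#'
#' @param target an `eigen_summary` (its `label` field is used for the class
#'   restriction).
#' @param candidates list of `eigen_summary` objects, excluding the target.
#' @param w an `eros_weights` object.
#' @param k neighbour count (default 5, following the original SMOTE
#'   implementation).
#' @param same_class_only restrict to candidates sharing the target's label
#'   (default `TRUE`).
#' @return Data frame with columns `index` (position in `candidates`) and
#'   `similarity`, ordered by decreasing similarity.
#' @export
eros_nearest_neighbors <- function(target, candidates, w, k = 5L,
                                   same_class_only = TRUE) {
  if (!is_scalar_number(k) || k < 1L)
    stop_fc("k must be >= 1", class = "fcdiag_parameter_error")
  labels <- vapply(candidates, function(e) e$label, integer(1))
  eligible <- if (same_class_only) which(labels == target$label)
              else seq_along(candidates)
  if (length(eligible) == 0L)
    stop_fc("no eligible neighbour for subject '%s'", target$subject_id,
            class = "fcdiag_empty_neighborhood_error")
  sims <- vapply(candidates[eligible], eros_similarity, numeric(1),
                 A = target, w = w)
  ord <- order(-sims, eligible)
  take <- utils::head(ord, k)
  if (length(take) < k)
    warning(sprintf("only %d eligible neighbour(s) for subject '%s' (k = %d)",
                    length(take), target$subject_id, k))
  data.frame(index = eligible[take], similarity = sims[take])
}
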