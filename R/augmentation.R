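# SMOTE-style data augmentation in masked-feature space, guided by EROS
# similarity.  For each real training sample, one of its k nearest
# same-class neighbours is drawn and a synthetic sample is placed at a
# uniformly random point on the segment between the two feature vectors.
# With one synthetic sample per real sample the training set doubles.

#' Augmentation configuration
#'
#' @param k neighbour count for the EROS kNN search (default 5).
#' @param per_sample_count synthetic samples generated per real sample
#'   (default 1, i.e. the training set doubles).
#' @param same_class_only restrict neighbours to the seed sample's class
#'   (default `TRUE`); synthetic samples inherit the seed sample's label.
#' @param seed RNG seed for reproducible draws, or `NULL`.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(k = 5L, per_sample_count = 1L,
                                same_class_only = TRUE, seed = NULL) {
  if (!is_scalar_number(k) || k < 1L)
    stop_fc("k must be >= 1", class = "fcdiag_parameter_error")
  if (!is_scalar_number(per_sample_count) || per_sample_count < 0L)
    stop_fc("per_sample_count must be >= 0", class = "fcdiag_parameter_error")
  structure(list(k = as.integer(k),
                 per_sample_count = as.integer(per_sample_count),
                 same_class_only = isTRUE(same_class_only), seed = seed),
            class = "augmentation_config")
}

#' Linear interpolation between two feature vectors
#'
#' Returns `alpha * p + (1 - alpha) * q`; each component lies between the
#' corresponding components of `p` and `q`.
#'
#' @param p,q numeric vectors of equal length.
#' @param alpha interpolation weight in \[0, 1\] (`1` returns `p`, `0`
#'   returns `q`).
#' @export
interpolate_features <- function(p, q, alpha) {
  if (length(p) != length(q))
    stop_fc("feature vectors differ in length (%d vs %d)",
            length(p), length(q), class = "fcdiag_shape_error")
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1)
    stop_fc("alpha must lie in [0, 1]", class = "fcdiag_domain_error")
  alpha * p + (1 - alpha) * q
}

#' Augment a training set by EROS-guided interpolation
#'
#' For each real sample i (in row order), and for each of
#' `config$per_sample_count` repetitions: its `config$k` nearest same-class
#' neighbours under EROS similarity are found, one neighbour j is drawn
#' uniformly, then `alpha ~ U(0, 1)` is drawn, and the synthetic vector
#' `alpha * x_i + (1 - alpha) * x_j` is emitted with label `label_i`.  The
#' RNG consumes exactly two draws per synthetic sample (neighbour, then
#' alpha), in sample order, so runs are reproducible from `config$seed`.
#'
#' A sample with no eligible neighbour is skipped with a warning, in which
#' case the output is smaller than `N * (1 + per_sample_count)` rows.
#'
#' @param features numeric matrix, one row per real training sample (masked
#'   feature vectors).
#' @param labels binary label vector aligned with `features` rows.
#' @param eigen list of `eigen_summary` objects aligned with `features`
#'   rows (used only for the neighbour search).
#' @param w an `eros_weights` object computed from the same training set.
#' @param config an [augmentation_config()].
#' @return List with `features` (real rows followed by synthetic rows),
#'   `labels`, and `provenance`: a data frame (`seed_index`,
#'   `neighbor_index`, `alpha`) with one row per synthetic sample, indices
#'   referring to rows of the input `features`.
#' @export
augment_training_set <- function(features, labels, eigen, w, config) {
  stopifnot(inherits(config, "augmentation_config"))
  features <- as.matrix(features)
  N <- nrow(features)
  if (N == 0L || length(labels) != N || length(eigen) != N)
    stop_fc("features, labels and eigen summaries must be aligned and non-empty",
            class = "fcdiag_shape_error")
  sim <- eros_similarity_matrix(eigen, w)
  lab <- as.integer(labels)
  synth <- vector("list", N * config$per_sample_count)
  prov <- vector("list", N * config$per_sample_count)
  n_out <- 0L
  with_seed(config$seed, {
    for (i in seq_len(N)) {
      eligible <- if (config$same_class_only) which(lab == lab[i]) else seq_len(N)
      eligible <- setdiff(eligible, i)
      for (rep in seq_len(config$per_sample_count)) {
        if (length(eligible) == 0L) {
          warning(sprintf("sample %d has no eligible neighbour; skipped", i))
          break
        }
        ord <- order(-sim[i, eligible], eligible)
        nn <- eligible[utils::head(ord, config$k)]
        j <- nn[sample.int(length(nn), 1L)]
        alpha <- stats::runif(1L)
        n_out <- n_out + 1L
        synth[[n_out]] <- interpolate_features(features[i, ], features[j, ], alpha)
        prov[[n_out]] <- data.frame(seed_index = i, neighbor_index = j,
                                    alpha = alpha)
      }
    }
  })
  synth_mat <- if (n_out > 0L) do.call(rbind, synth[seq_len(n_out)])
               else matrix(numeric(0), 0L, ncol(features))
  provenance <- if (n_out > 0L) do.call(rbind, prov[seq_len(n_out)])
                else data.frame(seed_index = integer(0),
                                neighbor_index = integer(0), alpha = numeric(0))
  list(features = rbind(features, synth_mat),
       labels = c(lab, lab[provenance$seed_index]),
       provenance = provenance)
}
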