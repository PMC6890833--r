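# Two-class multivariate Gaussian time-series generator with a known set
# of discriminative region pairs.
#
# Class 0 (controls) is drawn from a zero-mean Gaussian with unit-variance
# covariance Sigma0 whose off-diagonals sit at a background correlation
# level; class 1 (patients) uses Sigma1, identical except at the chosen
# perturbed pairs, whose correlations are shifted by +delta / -delta with
# alternating sign so both the positive and the negative arm of the
# extreme-correlation mask are exercised.  Every statistic the pipeline
# consumes (Pearson correlations, covariance eigenstructure) is therefore
# fully controlled by the generator.

#' Specification of a synthetic two-class connectivity dataset
#'
#' @param m region count (default 20).
#' @param timepoints scan length T (default 150).
#' @param n_per_class subjects per class (default 50).
#' @param n_pairs number of perturbed region pairs (default 12); ignored
#'   when `perturbed_pairs` is given explicitly.
#' @param perturbed_pairs optional 2-column matrix of region pairs
#'   (i < j); `NULL` (default) means `n_pairs` pairs are drawn from the
#'   seed.
#' @param delta covariance perturbation magnitude (default 0.6).
#' @param base_correlation background off-diagonal correlation
#'   (default 0.1).
#' @param n_sites number of pseudo-sites, assigned round-robin
#'   (default 1).
#' @param ar optional AR(1) coefficient in \[0, 1) for temporal smoothing;
#'   0 (default) gives temporally white series.  The stationary
#'   cross-regional covariance is preserved.
#' @param site_shift optional per-site mean offset (site s gets mean
#'   `site_shift * (s - 1)`) to emulate site heterogeneity (default 0).
#' @param seed RNG seed; the dataset is bit-reproducible from the spec and
#'   seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(m = 20L, timepoints = 150L, n_per_class = 50L,
                           n_pairs = 12L, perturbed_pairs = NULL,
                           delta = 0.6, base_correlation = 0.1,
                           n_sites = 1L, ar = 0, site_shift = 0, seed = 1L) {
  stopifnot(m >= 2L, timepoints >= 2L, n_per_class >= 1L, n_sites >= 1L,
            delta >= 0, ar >= 0, ar < 1)
  if (!is.null(perturbed_pairs)) {
    perturbed_pairs <- as.matrix(perturbed_pairs)
    if (ncol(perturbed_pairs) != 2L ||
        any(perturbed_pairs[, 1L] >= perturbed_pairs[, 2L]) ||
        any(perturbed_pairs > m) || any(perturbed_pairs < 1L))
      stop_fc("perturbed_pairs must be rows (i, j) with 1 <= i < j <= %d", m,
              class = "fcdiag_value_error")
    if (anyDuplicated(perturbed_pairs))
      stop_fc("perturbed_pairs must be unique", class = "fcdiag_value_error")
    n_pairs <- nrow(perturbed_pairs)
  }
  if (n_pairs > m * (m - 1L) / 2L)
    stop_fc("cannot place %d pairs among %d regions", n_pairs, m,
            class = "fcdiag_value_error")
  structure(list(m = as.integer(m), timepoints = as.integer(timepoints),
                 n_per_class = as.integer(n_per_class),
                 n_pairs = as.integer(n_pairs),
                 perturbed_pairs = perturbed_pairs, delta = delta,
                 base_correlation = base_correlation,
                 n_sites = as.integer(n_sites), ar = ar,
                 site_shift = site_shift, seed = seed),
            class = "synthetic_spec")
}

ridge_to_spd <- function(Sigma, min_eig = 1e-6, max_tries = 60L) {
  tries <- 0L
  while (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= min_eig) {
    if (tries >= max_tries) return(NULL)
    Sigma <- (Sigma + 0.01 * diag(nrow(Sigma))) / 1.01  # keeps unit diagonal
    tries <- tries + 1L
  }
  Sigma
}

draw_series <- function(TT, chol_Sigma, ar) {
  m <- ncol(chol_Sigma)
  Z <- matrix(stats::rnorm(TT * m), TT, m)
  if (ar > 0) {
    # AR(1) innovations scaled to preserve unit marginal variance
    for (t in 2:TT) Z[t, ] <- ar * Z[t - 1L, ] + sqrt(1 - ar^2) * Z[t, ]
  }
  Z %*% chol_Sigma
}

#' Generate a synthetic two-class dataset
#'
#' Draws `n_per_class` control and `n_per_class` patient subjects, each a
#' `timepoints x m` Gaussian series, from the class covariances described
#' in [synthetic_spec()].  Both covariance matrices are ridge-adjusted
#' towards the identity (preserving unit variances) if the perturbation
#' leaves them short of positive definite; an irreparable matrix raises an
#' error advising a smaller `delta`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (list of `roi_ts`, controls then patients,
#'   sites round-robin) and `truth`: the perturbed `pairs` matrix, their
#'   `signs`, their upper-triangle `pair_indices`, and the class
#'   covariances `Sigma0`, `Sigma1`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$m
  with_seed(spec$seed, {
    pairs <- spec$perturbed_pairs
    if (is.null(pairs) && spec$n_pairs > 0L) {
      # Draw pairs as disjoint <=2-edge paths over shuffled regions: the
      # signed perturbation then has spectral norm delta * sqrt(2), so the
      # patient covariance stays positive definite (no ridge distortion of
      # the planted effects) whenever delta < (1 - base_correlation)/sqrt(2).
      n_triples <- ceiling(spec$n_pairs / 2)
      if (3L * n_triples <= m) {
        regions <- sample.int(m, 3L * n_triples)
        pairs <- do.call(rbind, lapply(seq_len(n_triples), function(t) {
          r <- regions[(3L * t - 2L):(3L * t)]
          rbind(sort(r[1:2]), sort(r[2:3]))
        }))[seq_len(spec$n_pairs), , drop = FALSE]
      } else {
        # too many pairs for the disjoint-path layout: fall back to
        # unconstrained sampling (ridge adjustment may then engage)
        ut <- which(upper.tri(diag(m)), arr.ind = TRUE)
        ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
        pairs <- ut[sample.int(nrow(ut), spec$n_pairs), , drop = FALSE]
      }
      pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
      storage.mode(pairs) <- "integer"
      dimnames(pairs) <- NULL
    } else if (is.null(pairs)) {
      pairs <- matrix(integer(0), 0L, 2L)
    }
    signs <- rep_len(c(1, -1), nrow(pairs))

    Sigma0 <- matrix(spec$base_correlation, m, m); diag(Sigma0) <- 1
    Sigma1 <- Sigma0
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      Sigma1[i, j] <- Sigma1[j, i] <- Sigma0[i, j] + signs[p] * spec$delta
    }
    if (any(abs(Sigma1[upper.tri(Sigma1)]) >= 1))
      stop_fc("delta = %g pushes a correlation outside (-1, 1); use a smaller delta",
              spec$delta, class = "fcdiag_generation_error")
    Sigma0 <- ridge_to_spd(Sigma0)
    Sigma1 <- ridge_to_spd(Sigma1)
    if (is.null(Sigma0) || is.null(Sigma1))
      stop_fc("class covariance cannot be made positive definite; use a smaller delta",
              class = "fcdiag_generation_error")
    ch0 <- chol(Sigma0); ch1 <- chol(Sigma1)

    n_total <- 2L * spec$n_per_class
    width <- max(3L, nchar(n_total))
    sites <- paste0("SITE", rep_len(seq_len(spec$n_sites), n_total))
    dataset <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      label <- as.integer(s > spec$n_per_class)
      X <- draw_series(spec$timepoints, if (label == 1L) ch1 else ch0, spec$ar)
      site_no <- rep_len(seq_len(spec$n_sites), n_total)[s]
      if (spec$site_shift != 0)
        X <- X + spec$site_shift * (site_no - 1L)
      dataset[[s]] <- roi_timeseries(
        X, subject_id = sprintf("sub%0*d", width, s),
        label = label, site_id = sites[s])
    }
    list(dataset = dataset,
         truth = list(pairs = pairs, signs = signs,
                      pair_indices = if (nrow(pairs) > 0L)
                        pair_index(pairs[, 1L], pairs[, 2L], m)
                      else integer(0),
                      Sigma0 = Sigma0, Sigma1 = Sigma1))
  })
}

#' Fraction of ground-truth perturbed pairs recovered by a feature mask
#'
#' @param mask a `feature_mask` computed from a synthetic training set.
#' @param truth_pairs 2-column matrix of perturbed region pairs (i < j).
#' @param m region count of the generating spec.
#' @return Proportion in \[0, 1\]; an empty truth set recovers vacuously
#'   (1.0).
#' @export
mask_recovery_rate <- function(mask, truth_pairs, m) {
  stopifnot(inherits(mask, "feature_mask"))
  truth_pairs <- as.matrix(truth_pairs)
  if (nrow(truth_pairs) == 0L) return(1.0)
  idx <- pair_index(truth_pairs[, 1L], truth_pairs[, 2L], m)
  mean(idx %in% mask$indices)
}

#' Write a synthetic dataset in the on-disk formats the readers expect
#'
#' Writes one `<subject_id>.1D` file per subject, a `phenotype.csv`
#' (columns `SUB_ID`, `DX_GROUP` with the ABIDE convention 1 = patient /
#' 2 = control, `SITE_ID`) and a `truth.json` with the perturbed pairs.
#'
#' @param generated output of [make_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in generated$dataset)
    write_roi_timeseries(s, file.path(dir, paste0(s$subject_id, ".1D")))
  pheno <- data.frame(
    SUB_ID = vapply(generated$dataset, function(s) s$subject_id, character(1)),
    DX_GROUP = ifelse(vapply(generated$dataset, function(s) s$label, integer(1)) == 1L,
                      1L, 2L),
    SITE_ID = vapply(generated$dataset, function(s) s$site_id, character(1)))
  utils::write.csv(pheno, file.path(dir, "phenotype.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pairs = generated$truth$pairs, signs = generated$truth$signs,
         pair_indices = generated$truth$pair_indices),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
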