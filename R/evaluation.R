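# Stratified k-fold cross-validation orchestrating mask -> augmentation ->
# joint training -> prediction with strict train/test isolation, plus
# confusion metrics and ROC/AUC.
#
# Per fold, everything that is fitted (feature mask, EROS weights,
# augmentation, model) sees training subjects only; held-out subjects are
# scored with the training-fold mask and model.  Subjects are sorted by id
# before fold assignment, so results are invariant to input order.

#' Accuracy, sensitivity and specificity from binary labels
#'
#' `accuracy = (TP + TN) / N`, `sensitivity = TP / (TP + FN)` (patient
#' recall), `specificity = TN / (TN + FP)` (control recall).  A rate whose
#' denominator is zero is reported as `NA` rather than silently 0.
#'
#' @param y_true,y_pred aligned binary label vectors (1 = patient).
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop_fc("label vectors must be aligned and non-empty",
            class = "fcdiag_shape_error")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(accuracy = (tp + tn) / length(y_true),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp))
}

#' ROC curve and AUC by trapezoidal integration
#'
#' Sweeps all distinct score thresholds (prediction = score >= threshold)
#' and integrates the ROC curve with the trapezoidal rule.  Tied scores are
#' collapsed into a single threshold, which makes the trapezoidal area
#' equal the tie-aware concordance probability
#' `P(score+ > score-) + 0.5 * P(tie)`.
#'
#' @param y_true binary labels with at least one positive and one negative.
#' @param scores numeric scores (higher = more patient-like) aligned with
#'   `y_true`.
#' @return List with `auc` and `roc_points`, a data frame
#'   (`fpr`, `tpr`, `threshold`) from (0, 0) to (1, 1).
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores) || length(y_true) == 0L)
    stop_fc("labels and scores must be aligned and non-empty",
            class = "fcdiag_shape_error")
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_fc("ROC needs both classes present (got %d positive, %d negative)",
            n_pos, n_neg, class = "fcdiag_single_class_error")
  ord <- order(-scores)
  s <- scores[ord]; y <- y_true[ord]
  grp <- cumsum(!duplicated(s))            # runs of tied scores
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(auc = auc, roc_points = pts)
}

stratified_folds <- function(labels, k, sites = NULL) {
  fold <- integer(length(labels))
  strata <- if (is.null(sites)) as.character(labels)
            else paste(labels, sites, sep = "/")
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

feature_config <- function(fraction = 0.25, eros_n = 2L) {
  list(fraction = fraction, eros_n = as.integer(eros_n))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Subjects are sorted by id, then assigned to `k` folds stratified by
#' class label (optionally also by site).  Within each fold the feature
#' mask, the EROS weights and the model are fitted on training subjects
#' only; augmentation, when enabled, is applied to the training features
#' after the split.  Held-out subjects are scored with the training-fold
#' mask and model.
#'
#' @param dataset list of `roi_ts` objects with labels assigned.
#' @param k fold count (default 10 for pooled analyses; 5 is typical for
#'   small per-site datasets).  Each class must have at least `k` members.
#' @param train_config a [train_config()].
#' @param aug_config an [augmentation_config()], used when
#'   `augment = TRUE`.
#' @param fraction fraction of connectivity features kept per extreme by
#'   the mask (default 0.25).
#' @param eros_n eigen components per subject for EROS (default 2).
#' @param augment enable interpolation augmentation of training folds
#'   (default `TRUE`).
#' @param stratify_by_site also stratify fold assignment by site
#'   (default `FALSE`).
#' @param seed RNG seed governing fold assignment and all per-fold seeds.
#' @return An object of class `cv_result`: `folds` (one metrics row per
#'   fold), `mean` (averaged metrics), `details` (per fold: train/test
#'   subject ids, mask, EROS weights, augmentation provenance, loss
#'   trajectory, ROC points, scores) and `fold_assignment`.
#' @export
cross_validate <- function(dataset, k = 10L, train_config = fcdiag::train_config(),
                           aug_config = augmentation_config(),
                           fraction = 0.25, eros_n = 2L, augment = TRUE,
                           stratify_by_site = FALSE, seed = 1L) {
  if (!is_scalar_number(k) || k < 2L)
    stop_fc("k must be >= 2", class = "fcdiag_parameter_error")
  ids <- vapply(dataset, function(s) s$subject_id, character(1))
  dataset <- dataset[order(ids)]
  ids <- sort(ids)
  labels <- vapply(dataset, function(s) s$label, integer(1))
  sites <- vapply(dataset, function(s) s$site_id, character(1))
  if (any(is.na(labels)))
    stop_fc("all subjects need labels before cross-validation",
            class = "fcdiag_value_error")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop_fc("each class needs at least k = %d members (have %d controls, %d patients)",
            k, counts[["0"]], counts[["1"]], class = "fcdiag_stratification_error")

  seeds <- with_seed(seed, {
    fold <- stratified_folds(labels, k, if (stratify_by_site) sites)
    per_fold <- matrix(sample.int(.Machine$integer.max, 3L * k), nrow = k)
    list(fold = fold, per_fold = per_fold)
  })
  fold <- seeds$fold

  conn <- t(vapply(dataset, function(s) upper_triangle_vector(pearson_matrix(s$data)),
                   numeric(ncol(dataset[[1L]]$data) * (ncol(dataset[[1L]]$data) - 1L) / 2)))
  eigens <- lapply(dataset, covariance_eigen, n = eros_n)

  details <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    mask <- compute_mask(conn[tr, , drop = FALSE], fraction = fraction)
    F_tr <- conn[tr, mask$indices, drop = FALSE]
    F_te <- conn[te, mask$indices, drop = FALSE]
    y_tr <- labels[tr]

    w <- NULL; provenance <- NULL
    if (augment) {
      w <- eros_weights(eigens[tr], aggregate = "mean")
      acfg <- aug_config
      acfg$seed <- seeds$per_fold[f, 1L]
      aug <- augment_training_set(F_tr, y_tr, eigens[tr], w, acfg)
      F_tr <- aug$features; y_tr <- aug$labels
      provenance <- aug$provenance
    }

    tcfg <- train_config
    tcfg$seed <- seeds$per_fold[f, 2L]
    bdim <- tcfg$bottleneck_dim %||% max(1L, floor(ncol(F_tr) / 2))
    model <- hybrid_init(ncol(F_tr), bdim, seed = seeds$per_fold[f, 3L])
    trained <- hybrid_train(model, F_tr, y_tr, tcfg)
    tuned <- hybrid_finetune(trained$model, F_tr, y_tr, tcfg)

    probs <- hybrid_prob(tuned$model, F_te)
    preds <- as.integer(probs >= 0.5)
    cm <- confusion_metrics(labels[te], preds)
    roc <- roc_auc(labels[te], probs)
    rows[[f]] <- data.frame(fold = f, accuracy = cm$accuracy,
                            sensitivity = cm$sensitivity,
                            specificity = cm$specificity, auc = roc$auc)
    details[[f]] <- list(train_ids = ids[tr], test_ids = ids[te],
                         mask = mask, eros_weights = w,
                         provenance = provenance,
                         trajectory = trained$trajectory,
                         roc_points = roc$roc_points,
                         scores = data.frame(subject_id = ids[te],
                                             label = labels[te],
                                             prob = probs, pred = preds))
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    mean = data.frame(accuracy = mean(folds$accuracy, na.rm = TRUE),
                      sensitivity = mean(folds$sensitivity, na.rm = TRUE),
                      specificity = mean(folds$specificity, na.rm = TRUE),
                      auc = mean(folds$auc, na.rm = TRUE)),
    details = details,
    fold_assignment = data.frame(subject_id = ids, label = labels,
                                 site_id = sites, fold = fold),
    k = k, augment = augment, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (%s augmentation), seed %s\n",
              x$k, if (x$augment) "with" else "no", x$seed))
  print(x$folds, row.names = FALSE)
  cat("mean:\n")
  print(x$mean, row.names = FALSE)
  invisible(x)
}

#' Per-site cross-validation
#'
#' Runs [cross_validate()] independently within each acquisition site.  A
#' site in which some class has fewer than `k` members is skipped with a
#' message.  The `average` row is the unweighted mean over analysed sites.
#'
#' @inheritParams cross_validate
#' @param k fold count per site (default 5, suited to small sites).
#' @param ... further arguments passed to [cross_validate()].
#' @return An object of class `sitewise_result`: `per_site` (one mean row
#'   per analysed site), `average`, `skipped` (site ids), and the full
#'   `cv_result` per site in `results`.
#' @export
run_site_wise <- function(dataset, k = 5L, seed = 1L, ...) {
  sites <- vapply(dataset, function(s) s$site_id, character(1))
  out <- list(); skipped <- character(0)
  for (s in sort(unique(sites))) {
    sub <- dataset[sites == s]
    res <- tryCatch(cross_validate(sub, k = k, seed = seed, ...),
                    fcdiag_stratification_error = function(e) {
                      message(sprintf("site %s skipped: %s", s, conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) skipped <- c(skipped, s) else out[[s]] <- res
  }
  if (length(out) == 0L)
    stop_fc("no site satisfies the cross-validation preconditions",
            class = "fcdiag_stratification_error")
  per_site <- do.call(rbind, lapply(names(out), function(s)
    cbind(site = s, out[[s]]$mean)))
  average <- data.frame(site = "average",
                        accuracy = mean(per_site$accuracy),
                        sensitivity = mean(per_site$sensitivity),
                        specificity = mean(per_site$specificity),
                        auc = mean(per_site$auc))
  structure(list(per_site = per_site, average = average, skipped = skipped,
                 results = out),
            class = "sitewise_result")
}

#' @export
print.sitewise_result <- function(x, ...) {
  print(rbind(x$per_site, x$average), row.names = FALSE)
  if (length(x$skipped) > 0L)
    cat("skipped sites:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the full pipeline on an entire dataset
#'
#' Convenience wrapper for deployment-style use: computes the feature mask
#' on all provided subjects, optionally augments, trains jointly and
#' fine-tunes, and returns everything needed to score new subjects with
#' [predict_pipeline()].
#'
#' @inheritParams cross_validate
#' @return An object of class `fcdiag_fit` with `model`, `mask`,
#'   `eros_n` and the training loss `trajectory`.
#' @export
fit_pipeline <- function(dataset, train_config = fcdiag::train_config(),
                         aug_config = augmentation_config(),
                         fraction = 0.25, eros_n = 2L, augment = TRUE,
                         seed = 1L) {
  labels <- vapply(dataset, function(s) s$label, integer(1))
  conn <- t(vapply(dataset,
                   function(s) upper_triangle_vector(pearson_matrix(s$data)),
                   numeric(ncol(dataset[[1L]]$data) * (ncol(dataset[[1L]]$data) - 1L) / 2)))
  mask <- compute_mask(conn, fraction = fraction)
  F_all <- conn[, mask$indices, drop = FALSE]
  y <- labels
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3L))
  if (augment) {
    eigens <- lapply(dataset, covariance_eigen, n = eros_n)
    w <- eros_weights(eigens, aggregate = "mean")
    acfg <- aug_config; acfg$seed <- seeds[1L]
    aug <- augment_training_set(F_all, y, eigens, w, acfg)
    F_all <- aug$features; y <- aug$labels
  }
  tcfg <- train_config; tcfg$seed <- seeds[2L]
  bdim <- tcfg$bottleneck_dim %||% max(1L, floor(ncol(F_all) / 2))
  model <- hybrid_init(ncol(F_all), bdim, seed = seeds[3L])
  trained <- hybrid_train(model, F_all, y, tcfg)
  tuned <- hybrid_finetune(trained$model, F_all, y, tcfg)
  structure(list(model = tuned$model, mask = mask, eros_n = eros_n,
                 trajectory = trained$trajectory),
            class = "fcdiag_fit")
}

#' Score new subjects with a fitted pipeline
#'
#' @param fit a `fcdiag_fit` from [fit_pipeline()] or [load_model()].
#' @param dataset list of `roi_ts` objects.
#' @return Data frame with `subject_id`, `prob` (patient probability) and
#'   `pred` (thresholded label).
#' @export
predict_pipeline <- function(fit, dataset) {
  stopifnot(inherits(fit, "fcdiag_fit"))
  feats <- t(vapply(dataset, function(s)
    apply_mask(upper_triangle_vector(pearson_matrix(s$data)), fit$mask),
    numeric(length(fit$mask$indices))))
  probs <- hybrid_prob(fit$model, feats)
  data.frame(subject_id = vapply(dataset, function(s) s$subject_id, character(1)),
             prob = probs, pred = as.integer(probs >= 0.5))
}
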