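test_that("confusion metrics match hand counts and flag undefined rates", {
  y_true <- c(1, 1, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 0)     # TP=2 TN=3 FP=1 FN=0
  cm <- confusion_metrics(y_true, y_pred)
  expect_equal(cm$accuracy, 5 / 6)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 0.75)
  all_right <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(all_right), c(accuracy = 1, sensitivity = 1,
                                    specificity = 1))
  no_pos <- confusion_metrics(c(0, 0, 0), c(0, 1, 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_false(is.na(no_pos$specificity))
  expect_error(confusion_metrics(c(1, 0), c(1)), class = "fcdiag_shape_error")
})

test_that("trapezoidal AUC equals brute-force pairwise concordance", {
  concordance <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- expand.grid(p = pos, n = neg)
    mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
  }
  y <- c(1, 0, 1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.2)   # includes cross-class ties
  expect_equal(roc_auc(y, s)$auc, concordance(y, s), tolerance = 1e-12)
  withr::with_seed(17L, {
    for (rep in 1:20) {
      y <- rbinom(12, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(runif(12), 1)           # rounding forces ties
      expect_equal(roc_auc(y, s)$auc, concordance(y, s), tolerance = 1e-12)
    }
  })
})

test_that("AUC hits its degenerate anchors", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(.1, .2, .8, .9))$auc, 0.0)
  expect_error(roc_auc(c(1, 1), c(.5, .6)), class = "fcdiag_single_class_error")
})

test_that("ROC points are monotone and anchored at the corners", {
  withr::with_seed(3L, {
    y <- rep(c(1, 0), 10); s <- runif(20)
  })
  pts <- roc_auc(y, s)$roc_points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(tail(pts$fpr, 1), 1); expect_equal(tail(pts$tpr, 1), 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(23L, {
    y <- rep(c(1, 0), each = 15)
    s <- c(runif(15, 0.3, 1), runif(15, 0, 0.7))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("stratified folds partition both classes evenly", {
  gen <- tiny_dataset(n_per_class = 10L, seed = 2L)
  cv <- cross_validate(gen$dataset, k = 5L, train_config = tiny_train_config(),
                       augment = FALSE, seed = 1L)
  fa <- cv$fold_assignment
  expect_identical(nrow(fa), 20L)
  for (f in 1:5) {
    test_f <- fa[fa$fold == f, ]
    expect_identical(nrow(test_f), 4L)
    expect_identical(sum(test_f$label == 1L), 2L)  # 2 per class per fold
  }
  # coverage: union of test folds is the dataset, intersections empty
  expect_setequal(fa$subject_id, vapply(gen$dataset, function(s) s$subject_id,
                                        character(1)))
  expect_identical(anyDuplicated(fa$subject_id), 0L)
})

test_that("augmentation changes training size only, never test membership", {
  gen <- tiny_dataset(n_per_class = 8L, seed = 4L)
  on_ <- cross_validate(gen$dataset, k = 4L, train_config = tiny_train_config(),
                        augment = TRUE, seed = 9L)
  off <- cross_validate(gen$dataset, k = 4L, train_config = tiny_train_config(),
                        augment = FALSE, seed = 9L)
  expect_identical(on_$fold_assignment, off$fold_assignment)
  for (f in 1:4)
    expect_identical(on_$details[[f]]$test_ids, off$details[[f]]$test_ids)
  # provenance audit: all augmentation parents are training subjects
  for (f in 1:4) {
    prov <- on_$details[[f]]$provenance
    n_train <- length(on_$details[[f]]$train_ids)
    expect_true(all(prov$seed_index <= n_train))
    expect_true(all(prov$neighbor_index <= n_train))
    expect_identical(nrow(prov), n_train)   # doubling: one synthetic per real
  }
})

test_that("fold accuracy equals 1 - misclassification count / N exactly", {
  gen <- tiny_dataset(seed = 6L)
  cv <- cross_validate(gen$dataset, k = 3L, train_config = tiny_train_config(),
                       seed = 2L)
  for (f in 1:3) {
    sc <- cv$details[[f]]$scores
    expect_equal(cv$folds$accuracy[f],
                 1 - sum(sc$label != sc$pred) / nrow(sc), tolerance = 1e-15)
  }
  expect_equal(cv$mean$accuracy, mean(cv$folds$accuracy))
})

test_that("results are invariant to the order subjects are supplied in", {
  gen <- tiny_dataset(n_per_class = 6L, seed = 8L)
  cv1 <- cross_validate(gen$dataset, k = 3L, train_config = tiny_train_config(),
                        seed = 5L)
  perm <- withr::with_seed(1L, sample(length(gen$dataset)))
  cv2 <- cross_validate(gen$dataset[perm], k = 3L,
                        train_config = tiny_train_config(), seed = 5L)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
})

test_that("the fold mask is recomputable from training subjects alone", {
  gen <- tiny_dataset(n_per_class = 6L, seed = 10L)
  cv <- cross_validate(gen$dataset, k = 3L, train_config = tiny_train_config(),
                       seed = 3L)
  ids <- vapply(gen$dataset, function(s) s$subject_id, character(1))
  for (f in 1:3) {
    tr_ids <- cv$details[[f]]$train_ids
    vecs <- lapply(gen$dataset[match(tr_ids, ids)], function(s)
      upper_triangle_vector(pearson_matrix(s$data)))
    expect_identical(compute_mask(vecs)$indices, cv$details[[f]]$mask$indices)
    # EROS weights likewise derive from training subjects only
    eig <- lapply(gen$dataset[match(tr_ids, ids)], covariance_eigen, n = 2L)
    expect_equal(eros_weights(eig)$w, cv$details[[f]]$eros_weights$w,
                 tolerance = 1e-15)
  }
})

test_that("cross-validation preconditions are enforced", {
  gen <- tiny_dataset(n_per_class = 3L, seed = 1L)
  expect_error(cross_validate(gen$dataset, k = 5L),
               class = "fcdiag_stratification_error")
  expect_error(cross_validate(gen$dataset, k = 1L),
               class = "fcdiag_parameter_error")
  unlabelled <- gen$dataset
  unlabelled[[1]]$label <- NA_integer_
  expect_error(cross_validate(unlabelled, k = 2L),
               class = "fcdiag_value_error")
})

test_that("site-wise analysis runs per site and averages across them", {
  gen <- tiny_dataset(n_per_class = 8L, n_sites = 2L, seed = 13L)
  sw <- run_site_wise(gen$dataset, k = 2L, train_config = tiny_train_config())
  expect_identical(sort(sw$per_site$site), c("SITE1", "SITE2"))
  expect_equal(sw$average$accuracy, mean(sw$per_site$accuracy))
  expect_length(sw$skipped, 0L)
})

test_that("sites too small for stratified folds are skipped with a message", {
  gen <- tiny_dataset(n_per_class = 8L, n_sites = 2L, seed = 14L)
  small <- tiny_dataset(n_per_class = 2L, seed = 15L)$dataset
  small <- lapply(small, function(s) { s$site_id <- "TINY"
                                       s$subject_id <- paste0("t", s$subject_id); s })
  expect_message(
    sw <- run_site_wise(c(gen$dataset, small), k = 4L,
                        train_config = tiny_train_config()),
    "TINY skipped")
  expect_identical(sw$skipped, "TINY")
  expect_identical(sort(sw$per_site$site), c("SITE1", "SITE2"))
})
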