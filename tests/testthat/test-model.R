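# Helpers for gradient checking: flatten parameters, perturb, refit.
flatten_params <- function(model) {
  c(as.numeric(model$W_enc), model$b_enc, model$b_dec, model$W_slp, model$b_slp)
}
unflatten_params <- function(model, theta) {
  b <- model$bottleneck_dim; d <- model$input_dim
  i <- 0L
  model$W_enc <- matrix(theta[i + seq_len(b * d)], b, d); i <- i + b * d
  model$b_enc <- theta[i + seq_len(b)]; i <- i + b
  model$b_dec <- theta[i + seq_len(d)]; i <- i + d
  model$W_slp <- theta[i + seq_len(b)]; i <- i + b
  model$b_slp <- theta[i + 1L]
  model
}

test_that("initialization is reproducible and fan-in scaled", {
  m1 <- hybrid_init(8L, 3L, seed = 42L)
  m2 <- hybrid_init(8L, 3L, seed = 42L)
  expect_identical(m1, m2)
  expect_false(identical(m1, hybrid_init(8L, 3L, seed = 43L)))
  expect_true(all(abs(m1$W_enc) <= 1 / sqrt(8)))
  expect_identical(m1$b_enc, numeric(3))
  expect_error(hybrid_init(4L, 5L), class = "fcdiag_parameter_error")
})

test_that("encoding applies tanh with values strictly inside (-1, 1)", {
  m <- hybrid_init(4L, 2L, seed = 1L)
  m$W_enc[] <- 0; m$W_slp[] <- 0
  expect_equal(as.numeric(hybrid_encode(m, rep(1, 4))), c(0, 0))
  m1 <- hybrid_init(1L, 1L, seed = 1L)
  m1$W_enc[] <- 1; m1$b_enc[] <- 0
  expect_equal(as.numeric(hybrid_encode(m1, 0.5)), tanh(0.5))
  big <- hybrid_encode(hybrid_init(3L, 2L, seed = 2L), c(5, -5, 5))
  expect_true(all(abs(big) < 1))
  expect_error(hybrid_encode(m, rep(1, 5)), class = "fcdiag_shape_error")
})

test_that("decoding is linear and uses the tied (transposed) encoder weight", {
  m1 <- hybrid_init(1L, 1L, seed = 1L)
  m1$W_enc[] <- 2; m1$b_dec[] <- 1
  expect_equal(as.numeric(hybrid_decode(m1, 3)), 7)
  m <- hybrid_init(4L, 2L, seed = 3L)
  expect_equal(as.numeric(hybrid_decode(m, c(0, 0))), m$b_dec)
  # tying contract: changing the encoder weight changes the decoder output
  h <- c(0.3, -0.2)
  before <- hybrid_decode(m, h)
  m$W_enc[1, 1] <- m$W_enc[1, 1] + 1
  expect_false(isTRUE(all.equal(hybrid_decode(m, h), before)))
  expect_equal(hybrid_decode(m, h),
               matrix(h, 1) %*% m$W_enc + matrix(m$b_dec, 1))
})

test_that("the SLP head emits calibrated boundary probabilities", {
  m <- hybrid_init(4L, 2L, seed = 1L)
  m$W_slp[] <- 0; m$b_slp <- 0
  expect_equal(hybrid_prob(m, rnorm(4)), 0.5)
  expect_identical(hybrid_predict(m, rnorm(4)), 1L)  # f = 0.5 -> patient
  m$b_slp <- 50
  expect_gt(hybrid_prob(m, rnorm(4)), 1 - 1e-10)
  m$b_slp <- -0.1
  expect_identical(hybrid_predict(m, rnorm(4)), 0L)  # f < 0.5 -> control
})

test_that("the joint loss matches hand arithmetic on a 1-unit network", {
  m <- hybrid_init(1L, 1L, seed = 1L)
  m$W_enc[] <- 0.5; m$b_enc[] <- 0.1; m$b_dec[] <- 0.2
  m$W_slp[] <- 0.3; m$b_slp <- -0.1
  x <- 0.7; y <- 1
  h <- tanh(0.5 * 0.7 + 0.1)
  mse <- (0.5 * h + 0.2 - 0.7)^2
  ce <- -log(1 / (1 + exp(-(0.3 * h - 0.1))))
  expect_equal(hybrid_loss(m, x, y), mse + ce, tolerance = 1e-10)
  expect_equal(hybrid_loss(m, x, y, loss_weights = c(1, 0)), mse,
               tolerance = 1e-12)
  expect_equal(hybrid_loss(m, x, y, loss_weights = c(0, 1)), ce,
               tolerance = 1e-12)
})

test_that("a perfectly reconstructing, perfectly classifying model has ~0 loss", {
  m <- hybrid_init(2L, 2L, seed = 1L)
  m$W_enc <- diag(2) * 1e4        # tanh saturates at +/-1
  m$b_enc <- c(0, 0)
  m$W_slp <- c(100, 0); m$b_slp <- 0
  X <- matrix(c(1, -1), 1)        # encodes to ~(1, -1)
  h <- as.numeric(hybrid_encode(m, X))
  m$b_dec <- as.numeric(X) - as.numeric(h %*% m$W_enc)  # exact reconstruction
  expect_lt(hybrid_loss(m, X, 1), 1e-6)
})

test_that("analytic gradients match central finite differences", {
  m <- hybrid_init(4L, 2L, seed = 7L)
  X <- withr::with_seed(8L, matrix(rnorm(12, sd = 0.5), 3, 4))
  y <- c(1, 0, 1)
  g <- hybrid_gradients(m, X, y, loss_weights = c(1, 1))
  theta <- flatten_params(m)
  num <- numeric(length(theta))
  h <- 1e-5
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    num[i] <- (hybrid_loss(unflatten_params(m, tp), X, y) -
               hybrid_loss(unflatten_params(m, tm), X, y)) / (2 * h)
  }
  ana <- flatten_params(structure(c(g$grads, list(input_dim = m$input_dim,
                                                  bottleneck_dim = m$bottleneck_dim)),
                                  class = "hybrid_model"))
  denom <- pmax(abs(num), abs(ana), 1e-8)
  expect_lt(max(abs(ana - num) / denom), 1e-5)
  # the fine-tuning gradient matches finite differences of the CE term on
  # the SLP parameters (encoder gradients are deliberately frozen to zero)
  gce <- hybrid_gradients(m, X, y, ce_only = TRUE)$grads
  expect_identical(unname(unique(c(gce$W_enc, gce$b_enc, gce$b_dec))), 0)
  ce_loss <- function(mod) hybrid_loss(mod, X, y, loss_weights = c(0, 1))
  for (i in seq_along(m$W_slp)) {
    mp <- m; mp$W_slp[i] <- mp$W_slp[i] + h
    mm <- m; mm$W_slp[i] <- mm$W_slp[i] - h
    num_i <- (ce_loss(mp) - ce_loss(mm)) / (2 * h)
    expect_lt(abs(gce$W_slp[i] - num_i) / max(abs(num_i), 1e-8), 1e-5)
  }
})

test_that("joint training descends on separable data, reproducibly", {
  withr::with_seed(10L, {
    X <- rbind(matrix(rnorm(20, mean = 1, sd = 0.3), 10, 2),
               matrix(rnorm(20, mean = -1, sd = 0.3), 10, 2))
  })
  y <- rep(c(1, 0), each = 10)
  cfg <- train_config(joint_epochs = 40L, learning_rate = 0.02, seed = 3L)
  m <- hybrid_init(2L, 2L, seed = 3L)
  fit1 <- hybrid_train(m, X, y, cfg)
  fit2 <- hybrid_train(m, X, y, cfg)
  expect_identical(fit1, fit2)
  expect_lt(tail(fit1$trajectory, 1), fit1$trajectory[1])
  expect_length(fit1$trajectory, 40L)
  # minibatch mode shuffles but still descends
  cfgb <- train_config(joint_epochs = 40L, learning_rate = 0.02,
                       batch_size = 5L, seed = 3L)
  fitb <- hybrid_train(m, X, y, cfgb)
  expect_lt(tail(fitb$trajectory, 1), fitb$trajectory[1])
})

test_that("a zero learning rate leaves parameters untouched", {
  m <- hybrid_init(3L, 2L, seed = 5L)
  X <- toy_series(6L, 3L, seed = 6L)
  y <- rep(c(1, 0), 3)
  fit <- hybrid_train(m, X, y, train_config(joint_epochs = 4L,
                                            learning_rate = 0, seed = 1L))
  expect_identical(fit$model[c("W_enc", "b_enc", "b_dec", "W_slp", "b_slp")],
                   m[c("W_enc", "b_enc", "b_dec", "W_slp", "b_slp")])
  expect_equal(diff(range(fit$trajectory)), 0)
})

test_that("fine-tuning updates only the SLP head", {
  withr::with_seed(11L, {
    X <- rbind(matrix(rnorm(16, 1, 0.4), 8, 2),
               matrix(rnorm(16, -1, 0.4), 8, 2))
  })
  y <- rep(c(1, 0), each = 8)
  m <- hybrid_init(2L, 2L, seed = 1L)
  joint <- hybrid_train(m, X, y, train_config(joint_epochs = 10L,
                                              learning_rate = 0.01, seed = 2L))
  tuned <- hybrid_finetune(joint$model, X, y,
                           train_config(finetune_epochs = 10L,
                                        learning_rate = 0.01, seed = 2L))
  for (nm in c("W_enc", "b_enc", "b_dec"))
    expect_identical(tuned$model[[nm]], joint$model[[nm]])
  expect_false(identical(tuned$model$W_slp, joint$model$W_slp))
  # cross-entropy does not increase over fine-tuning on easy data
  ce <- function(mod) hybrid_loss(mod, X, y, loss_weights = c(0, 1))
  expect_lte(ce(tuned$model), ce(joint$model) + 1e-8)
  # zero fine-tune epochs is the identity
  same <- hybrid_finetune(joint$model, X, y,
                          train_config(finetune_epochs = 0L, seed = 2L))
  expect_identical(same$model, joint$model)
  expect_length(same$trajectory, 0L)
})

test_that("fitted pipelines serialize to JSON and score identically", {
  gen <- tiny_dataset(seed = 12L)
  fit <- fit_pipeline(gen$dataset, train_config = tiny_train_config(),
                      seed = 4L)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  expect_equal(back$model[c("W_enc", "b_enc", "b_dec", "W_slp", "b_slp")],
               fit$model[c("W_enc", "b_enc", "b_dec", "W_slp", "b_slp")],
               tolerance = 1e-14)
  expect_identical(back$mask, fit$mask)
  p1 <- predict_pipeline(fit, gen$dataset[1:4])
  p2 <- predict_pipeline(back, gen$dataset[1:4])
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})
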