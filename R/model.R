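# Tied-weight autoencoder jointly trained with a single-layer perceptron.
#
# Encoder:  h = tanh(W x + b_enc),            W: bottleneck x input
# Decoder:  x' = W' h + b_dec                 (decoder weight = t(W), tied;
#                                              never materialized separately)
# SLP:      f(x) = sigmoid(w_slp . h + b_slp)
#
# Joint loss = mse_weight * MSE(x, x') + ce_weight * BCE(y, f(x)).
# Gradients are analytic (the tied weight accumulates the encoder- and
# decoder-path terms) and optimized with Adam.  After joint training the
# SLP alone is fine-tuned on the cross-entropy term with the encoder
# frozen.

CLIP_EPS <- 1e-7

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Training configuration for the hybrid model
#'
#' @param bottleneck_dim hidden dimension; `NULL` (default) means
#'   `floor(input_dim / 2)`, continuing the halving pattern of the feature
#'   pipeline.
#' @param joint_epochs epochs of joint autoencoder + SLP training
#'   (default 25).
#' @param finetune_epochs epochs of SLP-only fine-tuning (default 5).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size minibatch size; `NULL` (default) means full batch,
#'   appropriate at desk scale.
#' @param loss_weights length-2 numeric `(mse_weight, ce_weight)`, default
#'   `c(1, 1)` (the two losses are simply added).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(bottleneck_dim = NULL, joint_epochs = 25L,
                         finetune_epochs = 5L, learning_rate = 1e-3,
                         batch_size = NULL, loss_weights = c(1, 1),
                         seed = NULL) {
  if (!is_scalar_number(joint_epochs) || joint_epochs < 0L)
    stop_fc("joint_epochs must be >= 0", class = "fcdiag_parameter_error")
  if (!is_scalar_number(finetune_epochs) || finetune_epochs < 0L)
    stop_fc("finetune_epochs must be >= 0", class = "fcdiag_parameter_error")
  if (!is_scalar_number(learning_rate) || learning_rate < 0)
    stop_fc("learning_rate must be >= 0", class = "fcdiag_parameter_error")
  if (length(loss_weights) != 2L || any(loss_weights < 0))
    stop_fc("loss_weights must be two non-negative numbers",
            class = "fcdiag_parameter_error")
  structure(list(bottleneck_dim = bottleneck_dim,
                 joint_epochs = as.integer(joint_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate, batch_size = batch_size,
                 loss_weights = as.numeric(loss_weights), seed = seed),
            class = "train_config")
}

#' Initialize hybrid model parameters
#'
#' Weights are drawn uniformly on `(-1/sqrt(fan_in), 1/sqrt(fan_in))`;
#' biases start at zero.  The decoder has no weight of its own: decoding
#' always uses the transpose of the current encoder weight.
#'
#' @param input_dim number of input features.
#' @param bottleneck_dim hidden dimension, `1 <= bottleneck_dim <=
#'   input_dim`.
#' @param seed RNG seed; identical seeds give identical parameters.
#' @return An object of class `hybrid_model`: `W_enc`
#'   (bottleneck x input), `b_enc`, `b_dec`, `W_slp` (length bottleneck),
#'   `b_slp`.
#' @export
hybrid_init <- function(input_dim, bottleneck_dim, seed = NULL) {
  if (!is_scalar_number(input_dim) || input_dim < 1L ||
      !is_scalar_number(bottleneck_dim) || bottleneck_dim < 1L ||
      bottleneck_dim > input_dim)
    stop_fc("need 1 <= bottleneck_dim <= input_dim (got %s, %s)",
            bottleneck_dim, input_dim, class = "fcdiag_parameter_error")
  input_dim <- as.integer(input_dim); bottleneck_dim <- as.integer(bottleneck_dim)
  with_seed(seed, {
    s1 <- 1 / sqrt(input_dim)
    s2 <- 1 / sqrt(bottleneck_dim)
    structure(list(
      W_enc = matrix(stats::runif(bottleneck_dim * input_dim, -s1, s1),
                     bottleneck_dim, input_dim),
      b_enc = numeric(bottleneck_dim),
      b_dec = numeric(input_dim),
      W_slp = stats::runif(bottleneck_dim, -s2, s2),
      b_slp = 0,
      input_dim = input_dim, bottleneck_dim = bottleneck_dim),
      class = "hybrid_model")
  })
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> %d -> %d (tied-weight autoencoder) -> 1 (SLP)\n",
              x$input_dim, x$bottleneck_dim))
  invisible(x)
}

as_row_matrix <- function(X, d) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != d)
    stop_fc("expected %d feature columns, got %d", d, ncol(X),
            class = "fcdiag_shape_error")
  X
}

#' Encode feature vectors to the bottleneck representation
#'
#' `h = tanh(W_enc x + b_enc)`; every component lies strictly in (-1, 1).
#'
#' @param model a `hybrid_model`.
#' @param X one feature vector or a matrix with one sample per row.
#' @return Matrix of bottleneck activations, one row per sample.
#' @export
hybrid_encode <- function(model, X) {
  X <- as_row_matrix(X, model$input_dim)
  tanh(sweep(X %*% t(model$W_enc), 2L, model$b_enc, "+"))
}

#' Decode bottleneck activations (tied weights, linear output)
#'
#' `x' = t(W_enc) h + b_dec`: the decoder weight is always the transpose of
#' the current encoder weight.
#'
#' @param model a `hybrid_model`.
#' @param H one bottleneck vector or a matrix with one sample per row.
#' @return Matrix of reconstructions, one row per sample.
#' @export
hybrid_decode <- function(model, H) {
  H <- as_row_matrix(H, model$bottleneck_dim)
  sweep(H %*% model$W_enc, 2L, model$b_dec, "+")
}

#' Patient-class probability from the SLP head
#'
#' `f(x) = sigmoid(W_slp . tanh(W_enc x + b_enc) + b_slp)`.
#'
#' @param model a `hybrid_model`.
#' @param X one feature vector or a matrix with one sample per row.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
hybrid_prob <- function(model, X) {
  H <- hybrid_encode(model, X)
  as.numeric(sigmoid(H %*% model$W_slp + model$b_slp))
}

#' Threshold probabilities into class labels
#'
#' A probability of exactly 0.5 maps to the patient class (boundary
#' inclusive).
#'
#' @param model a `hybrid_model`.
#' @param X one feature vector or a matrix with one sample per row.
#' @return Integer labels (1 = patient, 0 = control).
#' @export
hybrid_predict <- function(model, X) {
  as.integer(hybrid_prob(model, X) >= 0.5)
}

#' Joint reconstruction + classification loss
#'
#' `mse_weight * mean((x - x')^2) + ce_weight * mean(BCE)` where the MSE
#' mean runs over all matrix elements and BCE is binary cross-entropy with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param model a `hybrid_model`.
#' @param X sample matrix (one row per sample).
#' @param y binary labels aligned with rows of `X`.
#' @param loss_weights length-2 `(mse_weight, ce_weight)`.
#' @return Scalar loss.
#' @export
hybrid_loss <- function(model, X, y, loss_weights = c(1, 1)) {
  X <- as_row_matrix(X, model$input_dim)
  if (nrow(X) == 0L)
    stop_fc("empty batch", class = "fcdiag_empty_error")
  if (length(y) != nrow(X))
    stop_fc("labels not aligned with batch", class = "fcdiag_shape_error")
  H <- hybrid_encode(model, X)
  Xhat <- hybrid_decode(model, H)
  mse <- mean((X - Xhat)^2)
  p <- pmin(pmax(as.numeric(sigmoid(H %*% model$W_slp + model$b_slp)),
                 CLIP_EPS), 1 - CLIP_EPS)
  ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  loss_weights[1L] * mse + loss_weights[2L] * ce
}

#' Analytic gradients of the joint loss
#'
#' Returns the loss and its gradients with respect to every parameter.  The
#' tied encoder weight receives contributions from both the encoder and the
#' decoder path.  With `ce_only = TRUE` only the cross-entropy term is
#' differentiated (used for SLP fine-tuning).
#'
#' @param model a `hybrid_model`.
#' @param X sample matrix; `y` aligned binary labels.
#' @param y binary labels.
#' @param loss_weights length-2 `(mse_weight, ce_weight)`.
#' @param ce_only differentiate the classification term only.
#' @return List with `loss` and `grads` (named like the parameters).
#' @export
hybrid_gradients <- function(model, X, y, loss_weights = c(1, 1),
                             ce_only = FALSE) {
  X <- as_row_matrix(X, model$input_dim)
  N <- nrow(X); d <- model$input_dim
  if (N == 0L) stop_fc("empty batch", class = "fcdiag_empty_error")
  lw <- if (ce_only) c(0, loss_weights[2L]) else loss_weights
  H <- hybrid_encode(model, X)                       # N x b
  Xhat <- hybrid_decode(model, H)                    # N x d
  z <- as.numeric(H %*% model$W_slp + model$b_slp)
  p <- sigmoid(z)
  pc <- pmin(pmax(p, CLIP_EPS), 1 - CLIP_EPS)
  mse <- mean((X - Xhat)^2)
  ce <- mean(-(y * log(pc) + (1 - y) * log(1 - pc)))
  loss <- lw[1L] * mse + lw[2L] * ce

  G_rec <- (2 * lw[1L] / (N * d)) * (Xhat - X)       # dL/dXhat, N x d
  g_z <- (lw[2L] / N) * (p - y)                      # dL/dz, length N
  dH <- G_rec %*% t(model$W_enc) + outer(g_z, model$W_slp)   # N x b
  dPre <- dH * (1 - H^2)                             # through tanh
  grads <- list(
    W_enc = t(dPre) %*% X + t(H) %*% G_rec,          # encoder + decoder path
    b_enc = colSums(dPre),
    b_dec = colSums(G_rec),
    W_slp = as.numeric(t(H) %*% g_z),
    b_slp = sum(g_z))
  if (ce_only) {
    grads$W_enc[] <- 0; grads$b_enc[] <- 0; grads$b_dec[] <- 0
  }
  list(loss = loss, grads = grads)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

PARAM_NAMES <- c("W_enc", "b_enc", "b_dec", "W_slp", "b_slp")

run_epochs <- function(model, X, y, config, epochs, ce_only, update_names) {
  N <- nrow(X)
  bs <- config$batch_size %||% N
  state <- adam_state(model[update_names])
  t <- 0L
  trajectory <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    idx <- if (bs < N) sample.int(N) else seq_len(N)
    starts <- seq(1L, N, by = bs)
    for (s in starts) {
      b <- idx[s:min(s + bs - 1L, N)]
      gr <- hybrid_gradients(model, X[b, , drop = FALSE], y[b],
                             config$loss_weights, ce_only = ce_only)
      t <- t + 1L
      upd <- adam_step(model[update_names], gr$grads[update_names], state,
                       config$learning_rate, t)
      model[update_names] <- upd$params
      state <- upd$state
    }
    trajectory[epoch] <- hybrid_loss(model, X, y,
                                     if (ce_only) c(0, config$loss_weights[2L])
                                     else config$loss_weights)
    if (!is.finite(trajectory[epoch]))
      stop_fc("training diverged at epoch %d (non-finite loss)", epoch,
              class = "fcdiag_divergence_error")
  }
  list(model = model, trajectory = trajectory)
}

#' Jointly train the autoencoder and the SLP
#'
#' Runs `config$joint_epochs` Adam epochs on the summed reconstruction and
#' classification losses.  The tied-weight invariant holds throughout: the
#' decoder always uses the transpose of the current encoder weight.
#'
#' @param model a `hybrid_model` (typically from [hybrid_init()]).
#' @param X training sample matrix (one row per sample).
#' @param y binary labels aligned with rows of `X`.
#' @param config a [train_config()]; `config$seed` makes batch shuffling
#'   reproducible.
#' @return List with the trained `model` and the per-epoch full-batch loss
#'   `trajectory`.
#' @export
hybrid_train <- function(model, X, y, config = train_config()) {
  stopifnot(inherits(model, "hybrid_model"), inherits(config, "train_config"))
  X <- as_row_matrix(X, model$input_dim)
  if (length(y) != nrow(X))
    stop_fc("labels not aligned with samples", class = "fcdiag_shape_error")
  with_seed(config$seed,
            run_epochs(model, X, as.numeric(y), config, config$joint_epochs,
                       ce_only = FALSE, update_names = PARAM_NAMES))
}

#' Fine-tune the SLP head with the encoder frozen
#'
#' Runs `config$finetune_epochs` Adam epochs on the cross-entropy term
#' only, updating `W_slp` and `b_slp`; the encoder parameters (`W_enc`,
#' `b_enc`, `b_dec`) are left bit-for-bit unchanged.
#'
#' @inheritParams hybrid_train
#' @return List with the fine-tuned `model` and the per-epoch
#'   cross-entropy `trajectory`.
#' @export
hybrid_finetune <- function(model, X, y, config = train_config()) {
  stopifnot(inherits(model, "hybrid_model"), inherits(config, "train_config"))
  X <- as_row_matrix(X, model$input_dim)
  with_seed(config$seed,
            run_epochs(model, X, as.numeric(y), config,
                       config$finetune_epochs, ce_only = TRUE,
                       update_names = c("W_slp", "b_slp")))
}

#' Serialize / restore a fitted pipeline
#'
#' Stores model parameter arrays, the feature mask and configuration as a
#' single JSON archive, reloadable for prediction-only runs.
#'
#' @param fit a `fcdiag_fit` from [fit_pipeline()] or a bare
#'   `hybrid_model`.
#' @param path JSON file path.
#' @export
save_model <- function(fit, path) {
  if (inherits(fit, "hybrid_model")) fit <- list(model = fit)
  payload <- list(
    model = lapply(fit$model[PARAM_NAMES], function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    }),
    input_dim = fit$model$input_dim,
    bottleneck_dim = fit$model$bottleneck_dim,
    mask = if (!is.null(fit$mask)) unclass(fit$mask),
    eros_n = fit$eros_n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    W_enc = matrix(x$model$W_enc$data, x$model$W_enc$dim[1L], x$model$W_enc$dim[2L]),
    b_enc = as.numeric(x$model$b_enc$data),
    b_dec = as.numeric(x$model$b_dec$data),
    W_slp = as.numeric(x$model$W_slp$data),
    b_slp = as.numeric(x$model$b_slp$data),
    input_dim = as.integer(x$input_dim),
    bottleneck_dim = as.integer(x$bottleneck_dim)),
    class = "hybrid_model")
  mask <- if (!is.null(x$mask))
    structure(list(indices = as.integer(x$mask$indices),
                   q = as.integer(x$mask$q),
                   fraction = as.numeric(x$mask$fraction)),
              class = "feature_mask")
  structure(list(model = model, mask = mask,
                 eros_n = if (!is.null(x$eros_n)) as.integer(x$eros_n)),
            class = "fcdiag_fit")
}
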