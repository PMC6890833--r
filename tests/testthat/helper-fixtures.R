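# Shared fixture builders; everything is generated in code at test time.

# A small random ROI time series with reproducible content.
toy_series <- function(T = 10L, m = 6L, seed = 1L) {
  withr::with_seed(seed, matrix(rnorm(T * m), T, m))
}

# A T x 2 series whose *sample* covariance is exactly diag(v1, v2):
# two centred, orthogonal columns rescaled to the requested variances.
series_with_diag_cov <- function(v1, v2) {
  u <- c(-2, -1, 0, 1, 2)
  v <- c(1, -2, 0, 2, -1)          # centred, and sum(u * v) == 0
  cbind(u * sqrt(v1 / 2.5), v * sqrt(v2 / 2.5))
}

# A compact two-class dataset for harness tests: separable but cheap.
tiny_dataset <- function(n_per_class = 10L, m = 8L, T = 40L, delta = 0.6,
                         n_pairs = 4L, n_sites = 1L, seed = 1L) {
  make_dataset(synthetic_spec(m = m, timepoints = T,
                              n_per_class = n_per_class, n_pairs = n_pairs,
                              delta = delta, n_sites = n_sites, seed = seed))
}

# A fast training configuration for harness tests.
tiny_train_config <- function(...) {
  train_config(joint_epochs = 15L, finetune_epochs = 3L,
               learning_rate = 5e-3, ...)
}

# Direct transcription of the Pearson formula: sum of products of
# deviations over the root product of squared deviations.
brute_pearson <- function(u, v) {
  du <- u - mean(u); dv <- v - mean(v)
  sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
}
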