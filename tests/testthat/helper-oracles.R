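# Independent reference implementations used as oracles, plus small fixture
# builders.  These stay deliberately naive (loops, closed forms) so they are
# independent of the compiled path they check.

# Triple-loop scaled dot-product attention.
attn_oracle <- function(Q, K, V) {
  C <- nrow(Q); dk <- ncol(K)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      A[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    }
  }
  P <- matrix(0, C, C)
  for (i in seq_len(C)) {
    e <- exp(A[i, ] - max(A[i, ]))
    P[i, ] <- e / sum(e)
  }
  Z <- matrix(0, C, dk)
  for (i in seq_len(C)) {
    for (d in seq_len(dk)) {
      Z[i, d] <- sum(P[i, ] * V[, d])
    }
  }
  list(Z = Z, P = P)
}

# Per-sample tally of confusion-matrix metrics.
metrics_oracle <- function(confusion) {
  K <- nrow(confusion)
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  prec <- rec <- numeric(K)
  for (c in seq_len(K)) {
    tp <- confusion[c, c]
    fp <- sum(confusion[, c]) - tp
    fn <- sum(confusion[c, ]) - tp
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  list(accuracy = acc, precision = prec, recall = rec,
       precision_macro = mean(prec), recall_macro = mean(rec))
}

# Strip convolution of one channel with a fixed 1-D kernel through the full
# 2-D convolution oracle, cropped back to "same" size.
strip_oracle_1ch <- function(slice, kernel, direction) {
  km <- if (direction == "time") matrix(kernel, nrow = 1) else matrix(kernel, ncol = 1)
  full <- conv2d_full(slice, km)
  conv2d_same_crop(full, nrow(km), ncol(km))
}

# A tiny labelled dataset with class-dependent amplitude structure: fast to
# build, trivially learnable.  Returns a taste_dataset.
make_tiny_dataset <- function(n_per_class = 10, K = 3, H = 6, W = 16,
                              seed = 42, noise = 0.1) {
  set.seed(seed)
  n <- n_per_class * K
  x <- array(0, c(H, W, n))
  lab <- rep(seq_len(K) - 1L, each = n_per_class)
  tt <- seq_len(W) / W
  for (i in seq_len(n)) {
    amp <- 0.5 + lab[i]
    x[, , i] <- outer(rep(amp, H), sin(2 * pi * 4 * tt)) +
      matrix(rnorm(H * W, sd = noise), H, W)
  }
  meta <- tibble::tibble(sample = seq_len(n), label = lab,
                         subject = rep(1L, n), repetition = rep(1L, n),
                         epoch = seq_len(n))
  tastenet:::new_taste_dataset(x, meta)
}

# Matching tiny model configuration.
tiny_model_config <- function(H = 6, W = 16, K = 3, ...) {
  model_config(expansion_channels = 2L, n_efcm = 1L,
               branch_kernels = c(3L), fc1_units = 8L, n_classes = K,
               input_electrodes = H, input_samples = W, ...)
}

tiny_train_config <- function(...) {
  args <- list(...)
  do.call(train_config,
          utils::modifyList(list(epochs = 2L, batch_size = 10L, n_folds = 2L,
                                 micro_batch = 16L), args))
}

# Two-class synthetic spec small enough for fast end-to-end runs.
tiny_synthetic_spec <- function(...) {
  args <- list(...)
  do.call(synthetic_spec,
          utils::modifyList(list(n_subjects = 1L, n_classes = 2L,
                                 n_repetitions = 1L, epochs_per_recording = 2L,
                                 duration_s = 2,
                                 gain_per_class = c(0, 1.5),
                                 spread_radius = c(0.5, 0.9),
                                 onset_latency_s = c(0.2, 0.1)), args))
}
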