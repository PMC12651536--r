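#' Training configuration
#'
#' Cross-entropy loss with the Adam optimiser at learning rate 0.01,
#' 500 epochs with batch size 200, an 8:2 stratified train/test split and
#' 10-fold cross-validation are the defaults of record.
#' [desk_train_config()] scales the schedule down for a single CPU.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size for each Adam step.
#' @param n_folds Folds for cross-validation (>= 2).
#' @param split_ratio Train fraction of the stratified split (0 < r < 1).
#' @param seed Seed governing shuffling and weight draws.
#' @param micro_batch Largest number of epochs pushed through the compiled
#'   core at once (memory control; gradients are accumulated so results are
#'   independent of this value).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 500L,
                         batch_size = 200L, n_folds = 10L, split_ratio = 0.8,
                         seed = 1L, micro_batch = 32L) {
  assert_that(split_ratio > 0 && split_ratio < 1, "0 < split_ratio < 1 required")
  assert_that(n_folds >= 2, "n_folds must be >= 2")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(epochs >= 0, "epochs must be >= 0")
  structure(list(loss = "cross_entropy", optimizer = "adam",
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds), split_ratio = split_ratio,
                 seed = as.integer(seed), micro_batch = as.integer(micro_batch)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' @param ... Overrides forwarded to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 12L, batch_size = 32L, n_folds = 2L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Stratified train/test split
#'
#' Splits each class independently with a seeded shuffle so per-class
#' proportions are preserved to within one sample; the two parts are
#' disjoint.  `grouped_by_subject` keeps whole subjects on one side
#' (avoiding subject leakage) instead of stratifying epochs by class.
#'
#' @param ds A `taste_dataset`.
#' @param ratio Train fraction.
#' @param seed Shuffle seed.
#' @param grouped_by_subject Split subjects rather than epochs.
#' @return List with `train` and `test` datasets.
#' @export
stratified_split <- function(ds, ratio = 0.8, seed = 1L,
                             grouped_by_subject = FALSE) {
  assert_that(inherits(ds, "taste_dataset"), "ds must be a taste_dataset")
  assert_that(ratio > 0 && ratio < 1, "0 < ratio < 1 required")
  if (grouped_by_subject) {
    subjects <- sort(unique(ds$meta$subject))
    n_tr <- round(ratio * length(subjects))
    assert_that(n_tr >= 1 && n_tr < length(subjects),
                "too few subjects for a grouped split")
    tr_subj <- with_seed(mix_seed(seed, 17L), sample(subjects, n_tr))
    tr_idx <- which(ds$meta$subject %in% tr_subj)
    te_idx <- setdiff(seq_len(n_samples(ds)), tr_idx)
  } else {
    tr_idx <- integer(0)
    for (cl in sort(unique(ds$meta$label))) {
      idx <- which(ds$meta$label == cl)
      n_tr <- round(ratio * length(idx))
      assert_that(n_tr >= 1 && n_tr < length(idx),
                  sprintf("class %s has too few samples (%d) for ratio %.2f",
                          cl, length(idx), ratio))
      tr_idx <- c(tr_idx, with_seed(mix_seed(seed, 31L, cl),
                                    sample(idx, n_tr)))
    }
    tr_idx <- sort(tr_idx)
    te_idx <- setdiff(seq_len(n_samples(ds)), tr_idx)
  }
  list(train = dataset_subset(ds, tr_idx), test = dataset_subset(ds, te_idx))
}

#' Train a model with mini-batch Adam
#'
#' Mini-batch cross-entropy/Adam updates with a per-epoch seeded shuffle;
#' the loss trace records the mean training loss of every epoch.  Two runs
#' with the same model, data and configuration produce identical traces.
#'
#' @param model A `taste_model` from [build_model()].
#' @param ds A `taste_dataset` (labels 0-based).
#' @param config A [train_config()].
#' @param verbose Print the per-epoch loss.
#' @return A `taste_fit`: list with the trained `model`, `loss_trace`
#'   tibble (epoch, loss) and the configuration.
#' @export
train_model <- function(model, ds, config = train_config(), verbose = FALSE) {
  assert_that(inherits(model, "taste_model"), "model must be a taste_model")
  assert_that(inherits(ds, "taste_dataset"), "ds must be a taste_dataset")
  N <- n_samples(ds)
  assert_that(N >= 1, "cannot train on an empty dataset")
  y <- as.integer(ds$meta$label) + 1L
  assert_that(all(y >= 1 & y <= model$config$n_classes),
              "labels out of range for the model's n_classes")
  params <- model$params
  state <- adam_init(params)
  cfg <- model$config
  losses <- numeric(config$epochs)
  mb <- max(1L, config$micro_batch)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(mix_seed(config$seed, 7L, ep), sample.int(N))
    ep_loss <- 0
    starts <- seq(1L, N, by = config$batch_size)
    for (s in starts) {
      bidx <- ord[s:min(s + config$batch_size - 1L, N)]
      Bn <- length(bidx)
      g_acc <- NULL
      bloss <- 0
      for (ms in seq(1L, Bn, by = mb)) {
        cidx <- bidx[ms:min(ms + mb - 1L, Bn)]
        eng <- epochs_to_engine(ds$x[, , cidx, drop = FALSE])
        fw <- model_fwd(params, cfg, eng$X, eng$H, eng$W, eng$B,
                        training = TRUE)
        params <- fw$params  # running BN moments advance
        sm <- softmax_xent(fw$logits, y[cidx])
        if (!is.finite(sm$loss)) {
          abort(sprintf("NaN/Inf loss at epoch %d (batch starting %d): %s",
                        ep, s, "training diverged; lower the learning rate"))
        }
        w <- length(cidx) / Bn
        bloss <- bloss + w * sm$loss
        g <- model_bwd(sm$dlogits, fw, cfg)
        if (is.null(g_acc)) {
          g_acc <- flatten_params(g)
          if (w != 1) g_acc <- lapply(g_acc, function(a) a * w)
        } else {
          fg <- flatten_params(g)
          for (nm in names(g_acc)) g_acc[[nm]] <- g_acc[[nm]] + fg[[nm]] * w
        }
      }
      grads <- assign_flat(zero_like_tree(params), g_acc)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss * Bn
    }
    losses[ep] <- ep_loss / N
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
  }
  model$params <- params
  structure(list(model = model,
                 loss_trace = tibble::tibble(epoch = seq_len(config$epochs),
                                             loss = losses),
                 config = config),
            class = "taste_fit")
}

#' @export
print.taste_fit <- function(x, ...) {
  final <- if (nrow(x$loss_trace)) x$loss_trace$loss[nrow(x$loss_trace)] else NA
  cat(sprintf("<taste_fit: %d epoch(s), final training loss %.4f>\n",
              nrow(x$loss_trace), final))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' One-vs-rest tallies per class c: TP = M[c,c], FP = sum of column c off
#' the diagonal, FN = sum of row c off the diagonal, TN = remainder.
#' Accuracy is trace/total; precision = TP/(TP+FP) and recall = TP/(TP+FN)
#' per class (0 with a warning when the denominator is 0); macro scores are
#' unweighted class means.
#'
#' @param confusion K x K matrix of non-negative integer counts, rows =
#'   true class, columns = predicted class.
#' @return A `taste_metrics` object.
#' @examples
#' m <- compute_metrics(matrix(c(3, 1, 1, 5), 2, byrow = TRUE))
#' m$accuracy  # 0.8
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  assert_that(nrow(confusion) == ncol(confusion), "confusion matrix must be square")
  assert_that(all(confusion >= 0), "confusion entries must be non-negative")
  assert_that(all(abs(confusion - round(confusion)) < 1e-9),
              "confusion entries must be integer counts")
  K <- nrow(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warn(sprintf("%s undefined for class(es) %s; reporting 0", what,
                   paste(which(den == 0) - 1L, collapse = ", ")))
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  structure(list(confusion = confusion,
                 n = total,
                 accuracy = sum(tp) / total,
                 per_class = tibble::tibble(class = seq_len(K) - 1L,
                                            tp = tp, fp = fp, fn = fn, tn = tn,
                                            precision = precision,
                                            recall = recall),
                 precision_macro = mean(precision),
                 recall_macro = mean(recall)),
            class = "taste_metrics")
}

#' @export
print.taste_metrics <- function(x, ...) {
  cat(sprintf("<taste_metrics: n = %d, accuracy %.4f, macro precision %.4f, macro recall %.4f>\n",
              x$n, x$accuracy, x$precision_macro, x$recall_macro))
  invisible(x)
}

#' Evaluate a model on a labelled dataset
#'
#' Argmax over the logits gives predictions; the confusion matrix (rows =
#' true class, columns = predicted) is summarised by [compute_metrics()].
#'
#' @param model A `taste_model` or `taste_fit`.
#' @param ds A non-empty `taste_dataset`.
#' @param chunk Epochs per forward chunk (memory control).
#' @return A `taste_metrics` with the per-sample predictions in attribute
#'   `"predictions"`.
#' @export
evaluate <- function(model, ds, chunk = 64L) {
  if (inherits(model, "taste_fit")) model <- model$model
  assert_that(inherits(model, "taste_model"), "model must be a taste_model")
  assert_that(inherits(ds, "taste_dataset") && n_samples(ds) >= 1,
              "cannot evaluate on an empty dataset")
  N <- n_samples(ds)
  preds <- integer(N)
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    preds[idx] <- predict(model, ds$x[, , idx, drop = FALSE])
  }
  K <- model$config$n_classes
  lev <- seq_len(K) - 1L
  confusion <- as.matrix(table(factor(ds$meta$label, levels = lev),
                               factor(preds, levels = lev)))
  dimnames(confusion) <- list(true = lev, predicted = lev)
  m <- compute_metrics(confusion)
  attr(m, "predictions") <- tibble::tibble(sample = ds$meta$sample,
                                           truth = ds$meta$label,
                                           prediction = preds)
  m
}

#' Stratified k-fold cross-validation
#'
#' Partitions the training data into `n_folds` class-stratified folds; each
#' fold trains a freshly seeded model on the remaining folds and validates
#' on the held-out fold.  Fold metrics are reported individually and as
#' mean +/- sd.
#'
#' @param ds Training `taste_dataset`.
#' @param mconfig A [model_config()] (its `seed` is re-mixed per fold).
#' @param tconfig A [train_config()].
#' @param keep_models Keep every fold model (needed by
#'   [select_best_fold()]).
#' @param verbose Print fold progress.
#' @return A `taste_cv`: tibble of fold metrics plus fold models.
#' @export
kfold_cv <- function(ds, mconfig, tconfig, keep_models = TRUE,
                     verbose = FALSE) {
  assert_that(inherits(ds, "taste_dataset"), "ds must be a taste_dataset")
  k <- tconfig$n_folds
  counts <- table(ds$meta$label)
  assert_that(k <= min(counts),
              sprintf("n_folds = %d exceeds the smallest class count (%d)",
                      k, min(counts)))
  fold_of <- integer(n_samples(ds))
  for (cl in sort(unique(ds$meta$label))) {
    idx <- with_seed(mix_seed(tconfig$seed, 97L, cl),
                     sample(which(ds$meta$label == cl)))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows <- vector("list", k)
  models <- vector("list", k)
  metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dataset_subset(ds, which(fold_of != f))
    va <- dataset_subset(ds, which(fold_of == f))
    mcf <- mconfig
    mcf$seed <- mix_seed(mconfig$seed, 211L, f)
    tcf <- tconfig
    tcf$seed <- mix_seed(tconfig$seed, 223L, f)
    fit <- train_model(build_model(mcf), tr, tcf)
    m <- evaluate(fit, va)
    rows[[f]] <- tibble::tibble(fold = f, n_train = n_samples(tr),
                                n_val = n_samples(va),
                                accuracy = m$accuracy,
                                precision_macro = m$precision_macro,
                                recall_macro = m$recall_macro)
    metrics[[f]] <- m
    if (keep_models) models[[f]] <- fit$model
    if (verbose) {
      message(sprintf("fold %d/%d  val accuracy %.4f", f, k, m$accuracy))
    }
  }
  structure(list(folds = dplyr::bind_rows(rows), models = models,
                 metrics = metrics, fold_of = fold_of,
                 mconfig = mconfig, tconfig = tconfig),
            class = "taste_cv")
}

#' @export
print.taste_cv <- function(x, ...) {
  cat(sprintf("<taste_cv: %d folds, accuracy %.4f +/- %.4f>\n",
              nrow(x$folds), mean(x$folds$accuracy), stats::sd(x$folds$accuracy)))
  invisible(x)
}

#' Select the best cross-validation fold model
#'
#' Returns the fold model with the highest validation accuracy; ties are
#' broken by the lowest fold index.
#'
#' @param cv A `taste_cv` run with `keep_models = TRUE`.
#' @return The winning `taste_model`.
#' @export
select_best_fold <- function(cv) {
  assert_that(inherits(cv, "taste_cv"), "cv must be a taste_cv")
  assert_that(nrow(cv$folds) >= 1, "cross-validation has no folds")
  best <- which.max(cv$folds$accuracy)
  model <- cv$models[[best]]
  assert_that(!is.null(model), "kfold_cv must be run with keep_models = TRUE")
  attr(model, "fold") <- best
  model
}
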