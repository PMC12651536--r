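test_that("stratified_split preserves class proportions and is seeded", {
  ds <- make_tiny_dataset(n_per_class = 100, K = 3, H = 4, W = 8)
  sp <- stratified_split(ds, 0.8, seed = 1)
  expect_identical(n_samples(sp$train), 240L)
  expect_identical(n_samples(sp$test), 60L)
  expect_true(all(table(sp$train$meta$label) == 80L))
  expect_true(all(table(sp$test$meta$label) == 20L))
  # disjoint and exhaustive
  sp2 <- stratified_split(ds, 0.8, seed = 1)
  expect_identical(sp$train$x, sp2$train$x)
  sp3 <- stratified_split(ds, 0.8, seed = 2)
  expect_false(identical(sp$train$x, sp3$train$x))
  # a class too small for the ratio is rejected
  small <- dataset_subset(ds, c(1, 101:140, 201:240))
  expect_error(stratified_split(small, 0.8), "too few samples")
})

test_that("subject-grouped splits keep whole subjects on one side", {
  ds <- make_tiny_dataset(n_per_class = 20, K = 2, H = 4, W = 8)
  ds$meta$subject <- rep(1:5, 8)
  sp <- stratified_split(ds, 0.8, seed = 3, grouped_by_subject = TRUE)
  expect_length(intersect(unique(sp$train$meta$subject),
                          unique(sp$test$meta$subject)), 0)
  expect_identical(n_samples(sp$train) + n_samples(sp$test), 40L)
})

test_that("compute_metrics matches the hand example and rejects bad input", {
  m <- compute_metrics(matrix(c(3, 1, 1, 5), 2, byrow = TRUE))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class$precision[1], 0.75)
  expect_equal(m$per_class$recall[1], 0.75)
  # perfect diagonal
  mp <- compute_metrics(diag(c(4, 6, 2)))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$precision_macro, 1)
  expect_equal(mp$recall_macro, 1)
  # all predictions in class 0 on balanced 2-class data: class-1 recall 0
  expect_warning(mz <- compute_metrics(matrix(c(5, 0, 5, 0), 2, byrow = TRUE)),
                 "precision")
  expect_equal(mz$per_class$recall[2], 0)
  expect_error(compute_metrics(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("compute_metrics equals an independent tally on random confusions", {
  set.seed(17)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    conf <- matrix(rpois(K * K, lambda = 4), K)
    if (sum(conf) == 0) conf[1, 1] <- 1
    got <- suppressWarnings(compute_metrics(conf))
    want <- metrics_oracle(conf)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$per_class$precision, want$precision)
    expect_equal(got$per_class$recall, want$recall)
    expect_equal(got$precision_macro, want$precision_macro)
    expect_equal(got$recall_macro, want$recall_macro)
  }
})

test_that("training is deterministic and a zero learning rate freezes weights", {
  ds <- make_tiny_dataset(n_per_class = 8, K = 2)
  cfg <- tiny_model_config(K = 2, seed = 7)
  f1 <- train_model(build_model(cfg), ds, tiny_train_config(seed = 3))
  f2 <- train_model(build_model(cfg), ds, tiny_train_config(seed = 3))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$model$params, f2$model$params)
  m0 <- build_model(cfg)
  f0 <- train_model(m0, ds, tiny_train_config(learning_rate = 0, seed = 3))
  fl0 <- asNamespace("tastenet")$flatten_params(m0$params)
  fl1 <- asNamespace("tastenet")$flatten_params(f0$model$params)
  keep <- !grepl("rmean|rvar", names(fl0))  # BN moments are buffers, they move
  expect_equal(fl1[keep], fl0[keep])
})

test_that("one small Adam step decreases the single-batch loss in >= 95% of seeds", {
  ds <- make_tiny_dataset(n_per_class = 6, K = 2)
  wins <- 0
  for (s in 1:10) {
    cfg <- tiny_model_config(K = 2, seed = s)
    model <- build_model(cfg)
    tc <- tiny_train_config(epochs = 1L, batch_size = 12L,
                            learning_rate = 1e-3, seed = s)
    ns <- asNamespace("tastenet")
    eng <- ns$epochs_to_engine(ds$x)
    y <- as.integer(ds$meta$label) + 1L
    loss_of <- function(m) {
      fw <- ns$model_fwd(m$params, m$config, eng$X, eng$H, eng$W, eng$B, TRUE)
      ns$softmax_xent(fw$logits, y)$loss
    }
    before <- loss_of(model)
    fit <- train_model(model, ds, tc)
    after <- loss_of(fit$model)
    if (after <= before) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ds <- make_tiny_dataset(n_per_class = 6, K = 2)
  cfg <- tiny_model_config(K = 2, seed = 1)
  # a pathologically large step drives activations to Inf - Inf = NaN
  expect_error(train_model(build_model(cfg), ds,
                           tiny_train_config(learning_rate = 1e200,
                                             epochs = 3L)),
               "diverged|NaN")
})

test_that("k-fold CV partitions the data and reports per-fold metrics", {
  ds <- make_tiny_dataset(n_per_class = 12, K = 2)
  cv <- suppressWarnings(
    kfold_cv(ds, tiny_model_config(K = 2), tiny_train_config(n_folds = 3L)))
  expect_identical(nrow(cv$folds), 3L)
  # fold assignments are a partition
  expect_identical(sort(unique(cv$fold_of)), 1:3)
  expect_identical(length(cv$fold_of), 24L)
  expect_true(all(table(cv$fold_of, ds$meta$label) == 4L))  # stratified
  expect_identical(cv$folds$n_val, rep(8L, 3))
  # glance: sd of a constant metric is 0
  g <- glance(cv)
  expect_identical(g$n_folds, 3L)
  if (length(unique(cv$folds$accuracy)) == 1) expect_equal(g$accuracy_sd, 0)
  expect_error(kfold_cv(ds, tiny_model_config(K = 2),
                        tiny_train_config(n_folds = 13L)), "class count")
})

test_that("select_best_fold picks max accuracy with lowest-index ties", {
  fake <- structure(list(
    folds = tibble::tibble(fold = 1:3, accuracy = c(0.9, 0.95, 0.92)),
    models = lapply(1:3, function(i) structure(list(id = i),
                                               class = "taste_model"))),
    class = "taste_cv")
  expect_identical(select_best_fold(fake)$id, 2L)
  fake$folds$accuracy <- c(0.9, 0.9, 0.8)
  expect_identical(select_best_fold(fake)$id, 1L)
  fake1 <- structure(list(folds = fake$folds[1, ],
                          models = fake$models[1]), class = "taste_cv")
  expect_identical(select_best_fold(fake1)$id, 1L)
})

test_that("evaluate tallies a confusion matrix identical to a manual loop", {
  ds <- make_tiny_dataset(n_per_class = 10, K = 3)
  model <- build_model(tiny_model_config(seed = 5))
  m <- suppressWarnings(evaluate(model, ds))
  preds <- attr(m, "predictions")$prediction
  manual <- matrix(0L, 3, 3)
  for (i in seq_len(n_samples(ds))) {
    manual[ds$meta$label[i] + 1L, preds[i] + 1L] <-
      manual[ds$meta$label[i] + 1L, preds[i] + 1L] + 1L
  }
  expect_equal(unname(m$confusion), manual)
  # row sums equal per-class counts
  expect_equal(unname(rowSums(m$confusion)), rep(10, 3))
  oracle <- metrics_oracle(m$confusion)
  expect_equal(m$accuracy, oracle$accuracy)
  expect_equal(m$precision_macro, oracle$precision_macro)
  expect_error(evaluate(model, dataset_subset(ds, integer(0))), "empty")
})

test_that("a trained tiny model separates the tiny classes", {
  ds <- make_tiny_dataset(n_per_class = 15, K = 2)
  sp <- stratified_split(ds, 0.8, seed = 2)
  fit <- train_model(build_model(tiny_model_config(K = 2, seed = 2)),
                     sp$train, tiny_train_config(epochs = 8L, seed = 2))
  m <- evaluate(fit, sp$test)
  expect_gte(m$accuracy, 0.8)
  expect_true(all(diff(fit$loss_trace$loss[c(1, 8)]) < 0))
})
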