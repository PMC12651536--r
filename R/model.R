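#' Model configuration
#'
#' Describes the full architecture: a point-wise expansion of the raw
#' 1 x H x W epoch into `expansion_channels` learned channels, `n_efcm`
#' shape-preserving feature-computation blocks, a point-wise reduction to
#' `reduction_channels`, 1 x 2 pooling along time (W -> floor(W/2)), and two
#' dense layers (`fc1_units` then `n_classes` logits).  The defaults of
#' record are 40 expansion channels and 2 blocks with branch kernels 3/5/7,
#' a 128-unit first dense layer and 6 output classes.
#'
#' @param expansion_channels Learned channels after the expansion (>= 1).
#' @param n_efcm Number of feature-computation blocks (>= 1).
#' @param branch_kernels Odd strip-kernel sizes, one per branch.
#' @param branches Optional list of [branch_spec()]s overriding
#'   `branch_kernels` (used by the ablation grids).
#' @param reduction_channels Channels after the reduction (default 1).
#' @param pool_mode `"avg"` or `"max"` for the 1 x 2 temporal pooling.
#' @param fc1_units Width of the first dense layer.
#' @param n_classes Number of stimulus classes (>= 2).
#' @param input_electrodes,input_samples Input epoch geometry (21 x 256 for
#'   the default acquisition protocol).
#' @param strict_paper_mode Drop the batch-normalisation + ReLU
#'   stabilisation after each strip convolution, leaving the bare pipeline.
#' @param seed Seed for the weight initialisation.
#' @return A `model_config` object.
#' @export
model_config <- function(expansion_channels = 40L, n_efcm = 2L,
                         branch_kernels = c(3L, 5L, 7L), branches = NULL,
                         reduction_channels = 1L,
                         pool_mode = c("avg", "max"), fc1_units = 128L,
                         n_classes = 6L, input_electrodes = 21L,
                         input_samples = 256L, strict_paper_mode = FALSE,
                         seed = 1L) {
  pool_mode <- match.arg(pool_mode)
  assert_that(expansion_channels >= 1, "expansion_channels must be >= 1")
  assert_that(n_efcm >= 1, "n_efcm must be >= 1")
  assert_that(n_classes >= 2, "n_classes must be >= 2")
  assert_that(reduction_channels >= 1, "reduction_channels must be >= 1")
  assert_that(fc1_units >= 1, "fc1_units must be >= 1")
  assert_that(input_samples >= 2, "input_samples must be >= 2")
  if (is.null(branches)) {
    assert_that(all(vapply(branch_kernels, is_odd, logical(1))),
                "every branch kernel must be odd")
    branches <- default_branches(as.integer(branch_kernels))
  }
  assert_that(length(branches) >= 1, "at least one branch must be enabled")
  structure(list(expansion_channels = as.integer(expansion_channels),
                 n_efcm = as.integer(n_efcm),
                 branches = branches,
                 reduction_channels = as.integer(reduction_channels),
                 pool_mode = pool_mode,
                 fc1_units = as.integer(fc1_units),
                 n_classes = as.integer(n_classes),
                 input_electrodes = as.integer(input_electrodes),
                 input_samples = as.integer(input_samples),
                 strict_paper_mode = strict_paper_mode,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Desk-scale model configuration
#'
#' A reduced architecture (8 expansion channels, one block) sized so that a
#' full training run completes in well under a minute on a single CPU; the
#' documented defaults of record remain those of [model_config()].
#' @param ... Overrides forwarded to [model_config()].
#' @export
desk_model_config <- function(...) {
  args <- list(...)
  defaults <- list(expansion_channels = 8L, n_efcm = 1L)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Build a classification model from a configuration
#'
#' Initialises every learnable layer with the seeded uniform fan-in scheme.
#' Two builds from the same configuration produce identical weights.
#'
#' @param config A [model_config()].
#' @return A `taste_model` (configuration plus parameter tree).
#' @export
build_model <- function(config) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  H <- config$input_electrodes; W <- config$input_samples
  C <- config$expansion_channels
  flat_in <- config$reduction_channels * H * (W %/% 2L)
  params <- with_seed(config$seed, {
    list(expand = init_pw_params(C, 1L),
         blocks = lapply(seq_len(config$n_efcm),
                         function(i) init_block_params(C, config$branches)),
         reduce = init_pw_params(config$reduction_channels, C),
         fc1 = init_pw_params(config$fc1_units, flat_in),
         fc2 = init_pw_params(config$n_classes, config$fc1_units))
  })
  structure(list(config = config, params = params), class = "taste_model")
}

#' @export
print.taste_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<taste_model: %d channels, %d block(s), %d branch(es), ",
                     "%d x %d input, %d classes, %s parameters>\n"),
              cfg$expansion_channels, cfg$n_efcm, length(cfg$branches),
              cfg$input_electrodes, cfg$input_samples, cfg$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass: logits for a batch of epochs
#'
#' @param model A `taste_model`.
#' @param x Epochs as an H x W x B array (electrodes x time x samples) or a
#'   single H x W matrix.
#' @param training Use batch statistics in the normalisation layers.
#' @return A B x n_classes matrix of logits (batch order preserved).
#' @export
forward <- function(model, x, training = FALSE) {
  assert_that(inherits(model, "taste_model"), "model must be a taste_model")
  eng <- epochs_to_engine(x)
  cfg <- model$config
  assert_that(eng$H == cfg$input_electrodes && eng$W == cfg$input_samples,
              sprintf("input geometry %d x %d does not match the model (%d x %d)",
                      eng$H, eng$W, cfg$input_electrodes, cfg$input_samples))
  assert_that(all(is.finite(eng$X)), "input epochs must be finite")
  fw <- model_fwd(model$params, cfg, eng$X, eng$H, eng$W, eng$B, training)
  t(fw$logits)
}

#' Class predictions and probabilities
#'
#' @param object A `taste_model`.
#' @param x Epoch array as in [forward()].
#' @param type `"class"` for 0-based class labels, `"prob"` for the softmax
#'   matrix.
#' @param ... Unused.
#' @export
predict.taste_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  logits <- forward(object, x)
  if (type == "prob") {
    p <- t(softmax_cols(t(logits)))
    colnames(p) <- paste0("class_", seq_len(ncol(p)) - 1L)
    return(p)
  }
  max.col(logits, ties.method = "first") - 1L
}

#' Temporal pooling with a 1 x 2 kernel
#'
#' Non-overlapping 1 x 2 windows along the time axis: W -> floor(W/2), C and
#' H unchanged.  `"avg"` returns window means, `"max"` window maxima.
#'
#' @param x A [feature_map()] with W >= 2.
#' @param mode `"avg"` (default) or `"max"`.
#' @return The pooled `feature_map`.
#' @examples
#' temporal_pool(feature_map(matrix(c(1, 3, 5, 7), 1)))        # [2, 6]
#' temporal_pool(feature_map(matrix(c(1, 3, 5, 7), 1)), "max") # [3, 7]
#' @export
temporal_pool <- function(x, mode = c("avg", "max")) {
  mode <- match.arg(mode)
  x <- as_feature_map(x)
  d <- dim(x)
  assert_that(d[3] >= 2, "temporal pooling requires W >= 2")
  r <- tn_pool2_fwd(fm_to_mat(x), d[2], d[3], 1L, if (mode == "avg") 0L else 1L)
  mat_to_fm(r$Y, c(d[1], d[2], d[3] %/% 2L))
}

#' Count learnable parameters
#'
#' Total number of learnable scalars (batch-normalisation running moments
#' are buffers and excluded).
#'
#' @param model A `taste_model`, or a bare parameter tree.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "taste_model")) model$params else model
  n_learnable_params(p)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding a JSON echo of the configuration and the
#' named weight arrays.
#'
#' @param model A `taste_model`.
#' @param path File path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the restored `taste_model`.
#' @export
write_checkpoint <- function(model, path) {
  assert_that(inherits(model, "taste_model"), "model must be a taste_model")
  cfg <- model$config
  cfg_json <- jsonlite::toJSON(
    c(cfg[setdiff(names(cfg), "branches")],
      list(branches = lapply(cfg$branches, unclass))),
    auto_unbox = TRUE, digits = NA)
  saveRDS(list(config_json = as.character(cfg_json),
               weights = flatten_params(model$params)),
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  cj <- jsonlite::fromJSON(obj$config_json, simplifyVector = TRUE)
  branches <- lapply(seq_len(nrow(cj$branches)), function(i) {
    b <- cj$branches[i, ]
    branch_spec(index = b$index, kernel = b$kernel, directions = b$directions,
                use_conv = b$use_conv, use_attention = b$use_attention,
                use_residual = b$use_residual)
  })
  cfg <- model_config(expansion_channels = cj$expansion_channels,
                      n_efcm = cj$n_efcm, branches = branches,
                      reduction_channels = cj$reduction_channels,
                      pool_mode = cj$pool_mode, fc1_units = cj$fc1_units,
                      n_classes = cj$n_classes,
                      input_electrodes = cj$input_electrodes,
                      input_samples = cj$input_samples,
                      strict_paper_mode = cj$strict_paper_mode, seed = cj$seed)
  model <- build_model(cfg)
  model$params <- assign_flat(model$params, obj$weights)
  model
}
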