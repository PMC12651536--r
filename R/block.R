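#' Branch specification for a feature-computation block
#'
#' Each block runs up to three parallel branches.  A branch applies (1) local
#' strip convolutions (1 x k along time then k x 1 across electrodes)
#' followed by channel and spatial attention gates, (2) a residual connection
#' from the branch input, and (3) a global self-attention pass over the
#' learned channels, again with a residual.  The three toggles switch off
#' whole component groups for ablation: `use_conv` controls the local path
#' (strip convolutions plus both attention gates), `use_attention` the
#' channel-token self-attention, `use_residual` both residual additions.
#'
#' @param index Branch index (1, 2 or 3 by convention).
#' @param kernel Odd strip-kernel length; default mapping is branch 1 -> 3,
#'   2 -> 5, 3 -> 7.
#' @param directions Which strip-convolution factors the local path applies:
#'   `"both"` (1 x k then k x 1), `"time_only"` or `"space_only"`.
#' @param use_conv,use_attention,use_residual Component toggles.  A residual
#'   connection requires at least one partner component.
#' @return A `branch_spec` object.
#' @export
branch_spec <- function(index = 1L, kernel = c(3L, 5L, 7L)[index],
                        directions = c("both", "time_only", "space_only"),
                        use_conv = TRUE, use_attention = TRUE,
                        use_residual = TRUE) {
  directions <- match.arg(directions)
  assert_that(is.numeric(kernel) && length(kernel) == 1 && kernel >= 1 &&
                is_odd(kernel),
              "branch kernel must be a single odd positive integer")
  assert_that(!use_residual || use_conv || use_attention,
              "a residual connection requires convolution or self-attention")
  structure(list(index = as.integer(index), kernel = as.integer(kernel),
                 directions = directions, use_conv = use_conv,
                 use_attention = use_attention, use_residual = use_residual),
            class = "branch_spec")
}

#' Default three-branch configuration (kernels 3, 5 and 7)
#'
#' @param kernels Odd kernel sizes, one per branch.
#' @param ... Passed to [branch_spec()] for every branch.
#' @return List of [branch_spec()] objects.
#' @export
default_branches <- function(kernels = c(3L, 5L, 7L), ...) {
  lapply(seq_along(kernels),
         function(i) branch_spec(index = i, kernel = kernels[i], ...))
}

#' Initialise the parameters of one feature-computation block
#'
#' Draws all learnable weights with the seeded uniform fan-in scheme.
#'
#' @param channels Number of learned channels C carried through the block.
#' @param branches List of [branch_spec()] objects.
#' @param seed Integer seed for the weight draw.
#' @return An opaque parameter tree consumed by [efcm_forward()].
#' @export
efcm_params <- function(channels, branches = default_branches(), seed = 1L) {
  assert_that(length(branches) >= 1, "at least one branch must be enabled")
  with_seed(seed, init_block_params(channels, branches))
}

#' Forward pass of one feature-computation block
#'
#' Runs every enabled branch (local strip convolutions, channel and spatial
#' attention gates, residual, channel-token self-attention with residual),
#' concatenates the branch outputs along channels, and fuses them back to C
#' channels with a point-wise convolution.  Output dimensions always equal
#' input dimensions.
#'
#' @param x A [feature_map()] (C x H x W).
#' @param params Block parameters from [efcm_params()]; freshly initialised
#'   from `seed` when omitted.
#' @param branches List of [branch_spec()]s (at least one).
#' @param seed Seed used when `params` is missing.
#' @param batch_norm Apply batch normalisation + ReLU after each strip
#'   convolution (the stabilised default); `FALSE` gives the bare
#'   convolution pipeline.
#' @return A `feature_map` with the same C x H x W shape as `x`.
#' @examples
#' x <- feature_map(array(rnorm(2 * 4 * 8), c(2, 4, 8)))
#' dim(efcm_forward(x, branches = default_branches(c(3, 5, 7))))
#' @export
efcm_forward <- function(x, params = NULL, branches = default_branches(),
                         seed = 1L, batch_norm = TRUE) {
  x <- as_feature_map(x)
  assert_that(length(branches) >= 1, "at least one branch must be enabled")
  for (s in branches) assert_that(inherits(s, "branch_spec"),
                                  "branches must be branch_spec objects")
  d <- dim(x)
  if (is.null(params)) params <- efcm_params(d[1], branches, seed)
  r <- block_fwd(fm_to_mat(x), params, branches, d[2], d[3], 1L,
                 training = FALSE, use_bn = batch_norm)
  mat_to_fm(r$Y, d)
}
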