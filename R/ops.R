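#' Strip convolution (1 x k along time, or k x 1 across electrodes)
#'
#' Same-padded convolution whose kernel spans a single axis of the feature
#' map.  Stride is 1 and the symmetric zero padding is (k-1)/2, so H and W
#' are unchanged.  Semantics are true convolution (kernel flipped), matching
#' the discrete double-sum definition in [conv2d_full()]: with a frozen
#' kernel the output equals the centre crop of the full convolution applied
#' per channel.
#'
#' @param x A [feature_map()] (or C x H x W array).
#' @param kernel Either a length-k numeric vector, applied to every channel
#'   independently (no channel mixing), or a C_out x C_in x k array for a
#'   full channel-mixing convolution.  k must be odd.
#' @param direction `"time"` (1 x k) or `"space"` (k x 1).
#' @param bias Optional length-C_out bias (default zeros).
#' @return A `feature_map` of size C_out x H x W.
#' @examples
#' x <- feature_map(matrix(c(0, 3, 6, 9), 1))        # one row, W = 4
#' strip_conv(x, rep(1 / 3, 3), "time")              # [1, 3, 6, 5]
#' @export
strip_conv <- function(x, kernel, direction = c("time", "space"), bias = NULL) {
  x <- as_feature_map(x)
  direction <- match.arg(direction)
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  if (is.numeric(kernel) && is.null(dim(kernel))) {
    k <- length(kernel)
    cube <- array(0, c(C, C, k))
    for (n in seq_len(k)) cube[, , n] <- diag(kernel[n], C)
  } else {
    assert_that(length(dim(kernel)) == 3, "kernel must be a vector or a C_out x C_in x k array")
    assert_that(dim(kernel)[2] == C, "kernel input-channel dimension must match the feature map")
    cube <- kernel
    k <- dim(kernel)[3]
  }
  assert_that(is_odd(k), sprintf("strip kernel length must be odd, got %d", k))
  axis_len <- if (direction == "time") W else H
  assert_that(k <= axis_len,
              sprintf("kernel length %d exceeds the traversed axis (%d)", k, axis_len))
  co <- dim(cube)[1]
  if (is.null(bias)) bias <- numeric(co)
  y <- tn_strip_fwd(fm_to_mat(x), cube, bias, H, W, 1L, direction == "time")
  mat_to_fm(y, c(co, H, W))
}

#' Multi-branch local convolution (one branch)
#'
#' One branch of the local feature computation: a 1 x k strip convolution
#' along time followed by a k x 1 strip convolution across electrodes (or
#' only one of the two when the branch is restricted to a single direction,
#' as in the kernel-direction ablation).
#'
#' @param x A [feature_map()].
#' @param kernel_time,kernel_space Kernels as in [strip_conv()]; either may
#'   be omitted when `directions` excludes that factor.
#' @param directions `"both"`, `"time_only"` or `"space_only"`.
#' @return A `feature_map` with unchanged H and W.
#' @export
local_branch_conv <- function(x, kernel_time = NULL, kernel_space = NULL,
                              directions = c("both", "time_only", "space_only")) {
  directions <- match.arg(directions)
  y <- as_feature_map(x)
  if (directions %in% c("both", "time_only")) {
    assert_that(!is.null(kernel_time), "kernel_time is required")
    y <- strip_conv(y, kernel_time, "time")
  }
  if (directions %in% c("both", "space_only")) {
    assert_that(!is.null(kernel_space), "kernel_space is required")
    y <- strip_conv(y, kernel_space, "space")
  }
  y
}

#' Channel attention gate
#'
#' Per-channel multiplicative gating from pooled statistics: global average
#' pooling over H x W gives one statistic per channel; a single bias-free
#' 1-D convolution of length 3 (zero padding 1, stride 1) models local
#' cross-channel dependencies; a sigmoid squashes the result into (0,1)
#' weights that rescale each channel.
#'
#' @param x A [feature_map()] with C >= 1.
#' @param kernel Length-3 numeric vector, the shared 1-D convolution filter.
#' @return A `feature_map` of identical shape; attribute `"weights"` holds
#'   the per-channel gate values.
#' @export
channel_attention <- function(x, kernel) {
  x <- as_feature_map(x)
  assert_that(length(kernel) == 3, "channel-attention kernel must have length 3")
  d <- dim(x)
  res <- tn_chan_attn_fwd(fm_to_mat(x), as.numeric(kernel), d[2], d[3], 1L)
  out <- mat_to_fm(res$Y, d)
  attr(out, "weights") <- as.numeric(res$S)
  out
}

#' Spatial attention gate
#'
#' Per-position multiplicative gating from channel-pooled maps: the mean over
#' channels gives a 1 x H x W map; a same-padded 3 x 3 convolution models
#' local spatial structure; a sigmoid yields an (0,1) weight map that
#' rescales every channel position-wise.
#'
#' @param x A [feature_map()] with H >= 3 and W >= 3.
#' @param kernel 3 x 3 numeric matrix.
#' @param bias Scalar bias of the 3 x 3 convolution (default 0).
#' @return A `feature_map` of identical shape; attribute `"weights"` holds
#'   the H x W gate map.
#' @export
spatial_attention <- function(x, kernel, bias = 0) {
  x <- as_feature_map(x)
  assert_that(is.matrix(kernel) && all(dim(kernel) == c(3, 3)),
              "spatial-attention kernel must be 3 x 3")
  d <- dim(x)
  assert_that(d[2] >= 3 && d[3] >= 3,
              "spatial attention requires H >= 3 and W >= 3")
  res <- tn_spat_attn_fwd(fm_to_mat(x), kernel, bias, d[2], d[3], 1L)
  out <- mat_to_fm(res$Y, d)
  attr(out, "weights") <- matrix(res$m, d[2], d[3])
  out
}

#' Residual (element-wise) addition
#'
#' @param a,b Feature maps of identical shape.
#' @return Their element-wise sum as a `feature_map`.
#' @export
residual_add <- function(a, b) {
  a <- as_feature_map(a); b <- as_feature_map(b)
  assert_that(identical(dim(a), dim(b)), "residual_add requires identical shapes")
  feature_map(unclass(a) + unclass(b))
}

#' Query/key/value triple for channel-token self-attention
#'
#' @param Q,K,V Matrices of identical shape C x (H*W).
#' @return An `attention_triple` (list with Q, K, V and `d_k = H*W`).
#' @export
attention_triple <- function(Q, K, V) {
  assert_that(is.matrix(Q) && identical(dim(Q), dim(K)) && identical(dim(Q), dim(V)),
              "Q, K and V must be matrices of identical shape")
  assert_that(ncol(K) >= 1, "d_k must be positive")
  structure(list(Q = Q, K = K, V = V, d_k = ncol(K)), class = "attention_triple")
}

#' Point-wise projection to query, key and value
#'
#' Three independent 1 x 1 convolutions (C -> C, with bias, parameters not
#' shared) applied to a feature map, each result flattened to C x (H*W) in
#' the engine's electrode-major order.  These lightweight projections replace
#' large dense mappings when forming the self-attention inputs.
#'
#' @param x A [feature_map()].
#' @param w_q,w_k,w_v C x C projection matrices.
#' @param b_q,b_k,b_v Length-C biases (default zeros).
#' @return An [attention_triple()] with `d_k = H*W`; the source geometry is
#'   kept in attribute `"geom"` for the inverse reshape.
#' @export
pw_project <- function(x, w_q, w_k, w_v, b_q = NULL, b_k = NULL, b_v = NULL) {
  x <- as_feature_map(x)
  d <- dim(x); C <- d[1]
  for (w in list(w_q, w_k, w_v)) {
    assert_that(is.matrix(w) && ncol(w) == C, "projection matrices must have C columns")
  }
  z <- function(b) if (is.null(b)) numeric(C) else b
  m <- fm_to_mat(x)
  tr <- attention_triple(tn_pw_fwd(m, w_q, z(b_q)),
                         tn_pw_fwd(m, w_k, z(b_k)),
                         tn_pw_fwd(m, w_v, z(b_v)))
  attr(tr, "geom") <- d
  tr
}

#' Scaled dot-product self-attention
#'
#' `Z = softmax(Q K' / sqrt(d_k)) V` with the softmax taken row-wise over the
#' key axis, so each of the C channel tokens attends over all C tokens and
#' every softmax row sums to 1.
#'
#' @param Q An [attention_triple()], or the query matrix (C x d_k).
#' @param K,V Key and value matrices when `Q` is a matrix.
#' @return List with `Z` (C x d_k) and the attention matrix `P` (C x C).
#' @export
scaled_dot_attention <- function(Q, K = NULL, V = NULL) {
  if (inherits(Q, "attention_triple")) {
    tr <- Q
  } else {
    tr <- attention_triple(Q, K, V)
  }
  assert_that(tr$d_k >= 1, "d_k must be positive")
  res <- tn_attn_fwd(tr$Q, tr$K, tr$V, 1L, tr$d_k, 1L)
  list(Z = res$Z, P = matrix(res$P, nrow(tr$Q)))
}

#' Global feature branch (self-attention with residual)
#'
#' Projects a feature map to Q/K/V with point-wise convolutions, applies
#' scaled dot-product attention over the C channel tokens, reshapes Z back to
#' C x H x W (inverting the electrode-major flattening), and adds the branch
#' input as a residual.
#'
#' @param x A [feature_map()].
#' @param w_q,w_k,w_v,b_q,b_k,b_v Projection parameters as in [pw_project()].
#' @param residual Add the input back (default `TRUE`).
#' @return A `feature_map` of identical shape.
#' @export
global_branch <- function(x, w_q, w_k, w_v, b_q = NULL, b_k = NULL, b_v = NULL,
                          residual = TRUE) {
  x <- as_feature_map(x)
  d <- dim(x)
  tr <- pw_project(x, w_q, w_k, w_v, b_q, b_k, b_v)
  z <- scaled_dot_attention(tr)$Z
  zmap <- mat_to_fm(z, d)
  if (residual) residual_add(x, zmap) else zmap
}
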