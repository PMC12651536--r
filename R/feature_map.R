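#' Deep EEG feature map
#'
#' A feature map is a 3-D numeric array with dimensions C x H x W: C learned
#' channels, H electrode positions and W time samples.  Raw 1-s EEG epochs
#' enter the network as 1 x 21 x 256 maps; every operation inside a
#' feature-computation block preserves H and W (same-padding contract), so a
#' map's spatial geometry is fixed by the input epoch.
#'
#' @param values Numeric 3-D array (C x H x W), or a matrix (taken as
#'   1 x H x W).
#' @return A `feature_map` object (the array with a class attribute).
#' @examples
#' x <- feature_map(array(rnorm(2 * 4 * 8), c(2, 4, 8)))
#' dim(x)
#' @export
feature_map <- function(values) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  assert_that(is.array(values) && length(dim(values)) == 3,
              "a feature map must be a C x H x W array")
  assert_that(all(dim(values) >= 1L), "all feature-map dimensions must be >= 1")
  assert_that(all(is.finite(values)), "feature-map values must be finite")
  structure(values, class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_map: %d channel(s) x %d electrode(s) x %d time sample(s)>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @noRd
as_feature_map <- function(x) {
  if (inherits(x, "feature_map")) x else feature_map(x)
}

# feature_map (C x H x W) <-> engine matrix (C x H*W); see tastenet-package.R
fm_to_mat <- function(x) matrix(unclass(x), nrow = dim(x)[1])
mat_to_fm <- function(m, d) feature_map(array(m, d))

#' Full 2-D discrete convolution
#'
#' The textbook double-sum convolution of a P x Q matrix with an M x N
#' kernel, producing the complete (P+M-1) x (Q+N-1) output:
#' `W(i,j) = sum_m sum_n X(m,n) * Y(i-m, j-n)` over valid indices.  It is the
#' reference against which the network's same-padded strip convolutions are
#' checked: with a frozen kernel, a strip convolution must equal the centre
#' crop of this full convolution applied per channel.
#'
#' @param x Input matrix (P x Q).
#' @param y Kernel matrix (M x N).
#' @return The (P+M-1) x (Q+N-1) convolution matrix.
#' @examples
#' conv2d_full(matrix(c(1, 3, 2, 4), 2), diag(2))
#' @export
conv2d_full <- function(x, y) {
  assert_that(is.matrix(x) && is.matrix(y), "x and y must be matrices")
  assert_that(all(dim(x) >= 1) && all(dim(y) >= 1) && length(x) > 0 && length(y) > 0,
              "empty matrices are not convolvable")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "entries must be finite")
  P <- nrow(x); Q <- ncol(x); M <- nrow(y); N <- ncol(y)
  out <- matrix(0, P + M - 1, Q + N - 1)
  for (m in seq_len(P)) {
    for (n in seq_len(Q)) {
      out[m:(m + M - 1), n:(n + N - 1)] <-
        out[m:(m + M - 1), n:(n + N - 1)] + x[m, n] * y
    }
  }
  out
}

#' Centre crop of a full convolution to "same" size
#'
#' Helper for comparing a same-padded convolution (odd kernel, symmetric zero
#' padding) against [conv2d_full()].
#' @param w Full convolution output.
#' @param k_rows,k_cols Kernel dimensions (odd).
#' @return Matrix cropped back to the input size.
#' @export
conv2d_same_crop <- function(w, k_rows, k_cols) {
  pr <- (k_rows - 1) / 2; pc <- (k_cols - 1) / 2
  w[(1 + pr):(nrow(w) - pr), (1 + pc):(ncol(w) - pc), drop = FALSE]
}

#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the activation used to squash channel
#' and spatial attention statistics into (0,1) gating weights.  Saturates
#' numerically at the extremes rather than overflowing.
#'
#' @param x Numeric vector/array.
#' @return Values in (0,1), same shape as `x`.
#' @examples
#' sigmoid(0)   # 0.5
#' sigmoid(1)   # 0.7310586
#' @export
sigmoid <- function(x) {
  assert_that(all(is.finite(x)), "sigmoid input must be finite")
  1 / (1 + exp(-x))
}
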