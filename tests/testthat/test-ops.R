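test_that("strip_conv reproduces frozen-kernel hand examples", {
  x <- feature_map(matrix(c(0, 3, 6, 9), 1))
  expect_equal(as.vector(strip_conv(x, rep(1 / 3, 3), "time")), c(1, 3, 6, 5))
  # identity kernel (one-hot at centre) leaves any map unchanged
  set.seed(1)
  y <- feature_map(array(rnorm(3 * 5 * 8), c(3, 5, 8)))
  expect_equal(unclass(strip_conv(y, c(0, 1, 0), "time")), unclass(y))
  expect_equal(unclass(strip_conv(y, c(0, 1, 0), "space")), unclass(y))
  # zero kernel annihilates
  expect_true(all(strip_conv(y, c(0, 0, 0), "space") == 0))
})

test_that("strip_conv rejects invalid kernels", {
  x <- feature_map(array(0, c(1, 4, 4)))
  expect_error(strip_conv(x, c(1, 1), "time"), "odd")
  expect_error(strip_conv(x, rep(1, 5), "space"), "exceeds")
})

test_that("strip_conv equals the centre crop of the full-convolution oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    C <- sample(1:3, 1); H <- sample(3:8, 1); W <- sample(7:12, 1)
    k <- sample(c(3, 5, 7), 1)
    dir <- sample(c("time", "space"), 1)
    if (k > (if (dir == "time") W else H)) k <- 3
    x <- feature_map(array(rnorm(C * H * W), c(C, H, W)))
    kern <- rnorm(k)
    got <- strip_conv(x, kern, dir)
    for (c in seq_len(C)) {
      want <- strip_oracle_1ch(unclass(x)[c, , ], kern, dir)
      worst <- max(worst, max(abs(unclass(got)[c, , ] - want)))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("local_branch_conv composes the two strip factors in order", {
  set.seed(3)
  x <- feature_map(array(rnorm(1 * 4 * 4), c(1, 4, 4)))
  kt <- rnorm(3); ks <- rnorm(3)
  got <- local_branch_conv(x, kt, ks)
  step1 <- strip_oracle_1ch(unclass(x)[1, , ], kt, "time")
  want <- strip_oracle_1ch(step1, ks, "space")
  expect_equal(unclass(got)[1, , ], want, tolerance = 1e-10)
  # identity kernels pass the input through, singly or jointly
  idk <- c(0, 1, 0)
  expect_equal(unclass(local_branch_conv(x, idk, idk)), unclass(x))
  expect_equal(unclass(local_branch_conv(x, kernel_time = idk,
                                         directions = "time_only")),
               unclass(x))
})

test_that("channel attention gates channels by pooled statistics", {
  # zero input: weights are sigmoid(0) = 0.5, output stays zero
  z <- feature_map(array(0, c(3, 4, 4)))
  outz <- channel_attention(z, rnorm(3))
  expect_true(all(outz == 0))
  expect_equal(attr(outz, "weights"), rep(0.5, 3))
  # identity kernel [0,1,0]: channel c scaled by sigmoid(constant c)
  cst <- c(-1, 0.5, 2)
  x <- feature_map(array(rep(cst, 16), c(3, 4, 4)))
  out <- channel_attention(x, c(0, 1, 0))
  expect_equal(attr(out, "weights"), sigmoid(cst))
  expect_equal(unclass(out), unclass(x) * sigmoid(cst), tolerance = 1e-12,
               ignore_attr = TRUE)
  # hand convolution: pooled [1,2,3], kernel [.5,.5,.5] -> [1.5, 3, 2.5]
  x2 <- feature_map(array(rep(1:3, 4), c(3, 2, 2)))
  out2 <- channel_attention(x2, c(0.5, 0.5, 0.5))
  expect_equal(attr(out2, "weights"), sigmoid(c(1.5, 3, 2.5)))
})

test_that("spatial attention gates positions by channel-pooled maps", {
  z <- feature_map(array(0, c(2, 3, 3)))
  expect_true(all(spatial_attention(z, matrix(rnorm(9), 3)) == 0))
  # centre one-hot kernel: weight map = sigmoid(channel mean)
  set.seed(5)
  x <- feature_map(array(rnorm(2 * 4 * 5), c(2, 4, 5)))
  onehot <- matrix(0, 3, 3); onehot[2, 2] <- 1
  out <- spatial_attention(x, onehot)
  g <- apply(unclass(x), c(2, 3), mean)
  expect_equal(attr(out, "weights"), sigmoid(g), tolerance = 1e-12)
  expect_equal(unclass(out),
               sweep(unclass(x), c(2, 3), sigmoid(g), "*"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # ones kernel on a 3x3 map of ones: centre 9, corners 4, edges 6
  ones <- feature_map(array(1, c(1, 3, 3)))
  outw <- attr(spatial_attention(ones, matrix(1, 3, 3)), "weights")
  pre <- log(outw / (1 - outw))  # invert the sigmoid
  expect_equal(pre, matrix(c(4, 6, 4, 6, 9, 6, 4, 6, 4), 3), tolerance = 1e-9)
  expect_error(spatial_attention(feature_map(array(0, c(1, 2, 5))),
                                 matrix(1, 3, 3)), "H >= 3")
})

test_that("residual_add is exact element-wise addition with shape checks", {
  a <- feature_map(array(rnorm(8), c(1, 2, 4)))
  z <- feature_map(array(0, c(1, 2, 4)))
  expect_equal(unclass(residual_add(a, z)), unclass(a))
  expect_true(all(residual_add(a, feature_map(-unclass(a))) == 0))
  expect_equal(as.vector(residual_add(feature_map(array(c(1, 2), c(1, 1, 2))),
                                      feature_map(array(c(3, 4), c(1, 1, 2))))),
               c(4, 6))
  expect_error(residual_add(a, feature_map(array(0, c(1, 4, 2)))), "shape")
})

test_that("pw_project applies three independent 1x1 convolutions", {
  x <- feature_map(array(c(5, 7), c(2, 1, 1)))
  w <- matrix(c(1, 0, 1, 2), 2)  # [[1,1],[0,2]]
  tr <- pw_project(x, w, diag(2), diag(2))
  expect_equal(as.vector(tr$Q), c(12, 14))
  expect_equal(as.vector(tr$K), c(5, 7))
  expect_equal(tr$d_k, 1L)
  # identity projections: Q = K = V = flattened input
  set.seed(2)
  y <- feature_map(array(rnorm(3 * 2 * 4), c(3, 2, 4)))
  tri <- pw_project(y, diag(3), diag(3), diag(3))
  expect_equal(tri$Q, matrix(unclass(y), 3))
  expect_equal(tri$Q, tri$V)
  # zero weights with bias b: constant rows
  trb <- pw_project(y, matrix(0, 3, 3), diag(3), diag(3), b_q = c(1, 2, 3))
  expect_equal(trb$Q, matrix(rep(c(1, 2, 3), 8), 3))
})

test_that("scaled_dot_attention matches hand examples and the loop oracle", {
  # C = 1: softmax of 1x1 is 1, Z = V
  v <- matrix(rnorm(6), 1)
  expect_equal(scaled_dot_attention(matrix(rnorm(6), 1), matrix(rnorm(6), 1),
                                    v)$Z, v)
  # Q = 0: uniform rows, Z rows = column means of V
  V <- matrix(rnorm(12), 3)
  r0 <- scaled_dot_attention(matrix(0, 3, 4), matrix(rnorm(12), 3), V)
  expect_equal(r0$Z, matrix(rep(colMeans(V), each = 3), 3), tolerance = 1e-12)
  # d_k = 1 hand case
  r <- scaled_dot_attention(matrix(c(1, 0), 2), matrix(c(1, 0), 2),
                            matrix(c(10, 20), 2))
  e <- exp(1) / (exp(1) + 1)
  expect_equal(r$Z, matrix(c(e * 10 + (1 - e) * 20, 15), 2), tolerance = 1e-9)
  expect_equal(r$P[1, ], c(0.7311, 0.2689), tolerance = 1e-4)
})

test_that("vectorised attention equals the triple-loop oracle with unit-sum rows", {
  set.seed(11)
  worst <- 0
  for (i in 1:50) {
    C <- sample(1:4, 1); dk <- sample(1:8, 1)
    Q <- matrix(rnorm(C * dk), C); K <- matrix(rnorm(C * dk), C)
    V <- matrix(rnorm(C * dk), C)
    got <- scaled_dot_attention(Q, K, V)
    want <- attn_oracle(Q, K, V)
    worst <- max(worst, max(abs(got$Z - want$Z)), max(abs(got$P - want$P)))
    expect_equal(rowSums(got$P), rep(1, C), tolerance = 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("global_branch is the identity when the value projection is zero", {
  set.seed(4)
  x <- feature_map(array(rnorm(3 * 4 * 5), c(3, 4, 5)))
  out <- global_branch(x, w_q = matrix(rnorm(9), 3), w_k = matrix(rnorm(9), 3),
                       w_v = matrix(0, 3, 3))
  expect_equal(unclass(out), unclass(x), tolerance = 1e-12)
})

test_that("global_branch equals explicit flatten/attend/unflatten", {
  set.seed(9)
  x <- feature_map(array(rnorm(2 * 2 * 3), c(2, 2, 3)))
  wq <- matrix(rnorm(4), 2); wk <- matrix(rnorm(4), 2); wv <- matrix(rnorm(4), 2)
  got <- global_branch(x, wq, wk, wv)
  flat <- matrix(unclass(x), 2)
  z <- attn_oracle(wq %*% flat, wk %*% flat, wv %*% flat)$Z
  want <- unclass(x) + array(z, dim(x))
  expect_equal(unclass(got), want, tolerance = 1e-9)
  expect_identical(dim(got), dim(x))
})
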