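# Internal training engine: parameter trees, layer orchestration and the
# forward/backward passes over the compiled kernels.  All functions here are
# internal; the exported surface lives in block.R / model.R / train.R.
#
# Parameter trees are nested named lists whose leaves are numeric arrays.
# Batch-normalisation running moments are leaves named rmean/rvar and are
# buffers, not learnable parameters.

BN_MOMENTUM <- 0.1
BN_EPS <- 1e-5

# ---- initialisers -----------------------------------------------------------

init_pw_params <- function(c_out, c_in) {
  list(W = matrix(init_uniform(c(c_out, c_in), c_in), c_out, c_in),
       b = as.numeric(init_uniform(c_out, c_in)))
}

init_strip_params <- function(c_out, c_in, k) {
  list(W = init_uniform(c(c_out, c_in, k), c_in * k),
       b = as.numeric(init_uniform(c_out, c_in * k)))
}

init_bn_params <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), rmean = rep(0, C), rvar = rep(1, C))
}

init_branch_params <- function(C, k) {
  list(conv_t = init_strip_params(C, C, k),
       bn_t   = init_bn_params(C),
       conv_s = init_strip_params(C, C, k),
       bn_s   = init_bn_params(C),
       ca     = list(w = as.numeric(init_uniform(3, 3))),
       sa     = list(W = matrix(init_uniform(c(3, 3), 9), 3, 3),
                     b = as.numeric(init_uniform(1, 9))),
       pq     = init_pw_params(C, C),
       pk     = init_pw_params(C, C),
       pv     = init_pw_params(C, C))
}

init_block_params <- function(C, specs) {
  branches <- lapply(specs, function(s) init_branch_params(C, s$kernel))
  list(branches = branches, fuse = init_pw_params(C, length(specs) * C))
}

# ---- parameter-tree utilities ----------------------------------------------

flatten_params <- function(p) {
  out <- list()
  rec <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) rec(x[[nm]], c(path, nm))
    } else {
      out[[paste(path, collapse = ".")]] <<- x
    }
  }
  rec(p, character())
  out
}

assign_flat <- function(p, flat) {
  rec <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) x[[nm]] <- rec(x[[nm]], c(path, nm))
      x
    } else {
      flat[[paste(path, collapse = ".")]]
    }
  }
  rec(p, character())
}

zero_like_tree <- function(p) {
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec)
    else if (is.null(dim(x))) numeric(length(x))
    else array(0, dim(x))
  }
  rec(p)
}

is_buffer_name <- function(nm) grepl("(^|\\.)(rmean|rvar)$", nm)

n_learnable_params <- function(p) {
  fl <- flatten_params(p)
  sum(vapply(fl[!is_buffer_name(names(fl))], length, integer(1)))
}

# ---- branch forward/backward ------------------------------------------------

branch_fwd <- function(X, bp, spec, H, W, B, training, use_bn) {
  cache <- list()
  X0 <- X
  cur <- X
  if (spec$use_conv) {
    if (spec$directions != "space_only") {
      cache$ct_in <- cur
      cur <- tn_strip_fwd(cur, bp$conv_t$W, bp$conv_t$b, H, W, B, TRUE)
      if (use_bn) {
        r <- tn_bn_fwd(cur, bp$bn_t$gamma, bp$bn_t$beta, bp$bn_t$rmean,
                       bp$bn_t$rvar, BN_MOMENTUM, training, BN_EPS, TRUE)
        bp$bn_t$rmean <- as.numeric(r$rmean); bp$bn_t$rvar <- as.numeric(r$rvar)
        cache$bn_t <- list(xhat = r$xhat, invstd = as.numeric(r$invstd),
                           Y = r$Y)
        cur <- r$Y
      }
    }
    if (spec$directions != "time_only") {
      cache$cs_in <- cur
      cur <- tn_strip_fwd(cur, bp$conv_s$W, bp$conv_s$b, H, W, B, FALSE)
      if (use_bn) {
        r <- tn_bn_fwd(cur, bp$bn_s$gamma, bp$bn_s$beta, bp$bn_s$rmean,
                       bp$bn_s$rvar, BN_MOMENTUM, training, BN_EPS, TRUE)
        bp$bn_s$rmean <- as.numeric(r$rmean); bp$bn_s$rvar <- as.numeric(r$rvar)
        cache$bn_s <- list(xhat = r$xhat, invstd = as.numeric(r$invstd),
                           Y = r$Y)
        cur <- r$Y
      }
    }
    cache$ca_in <- cur
    ca <- tn_chan_attn_fwd(cur, bp$ca$w, H, W, B)
    cache$ca <- list(P = ca$P, S = ca$S)
    cache$sa_in <- ca$Y
    sa <- tn_spat_attn_fwd(ca$Y, bp$sa$W, bp$sa$b, H, W, B)
    cache$sa <- list(g = as.numeric(sa$g), m = as.numeric(sa$m))
    cur <- sa$Y
  } else {
    cur <- X0
  }
  Xi3 <- if (spec$use_residual) X0 + cur else cur
  if (spec$use_attention) {
    cache$attn_in <- Xi3
    C <- nrow(Xi3)
    QKV <- tn_pw_fwd(Xi3, rbind(bp$pq$W, bp$pk$W, bp$pv$W),
                     c(bp$pq$b, bp$pk$b, bp$pv$b))
    Q <- QKV[seq_len(C), , drop = FALSE]
    K <- QKV[C + seq_len(C), , drop = FALSE]
    V <- QKV[2L * C + seq_len(C), , drop = FALSE]
    at <- tn_attn_fwd(Q, K, V, H, W, B)
    cache$attn <- list(Q = Q, K = K, V = V, P = at$P)
    Y <- if (spec$use_residual) Xi3 + at$Z else at$Z
  } else {
    Y <- Xi3
  }
  list(Y = Y, cache = cache, bp = bp)
}

branch_bwd <- function(dY, cache, bp, spec, H, W, B, use_bn) {
  g <- zero_like_tree(bp)
  if (spec$use_attention) {
    a <- cache$attn
    dZ <- dY
    dXi3 <- if (spec$use_residual) dY else matrix(0, nrow(dY), ncol(dY))
    ab <- tn_attn_bwd(a$Q, a$K, a$V, a$P, dZ, H, W, B)
    C <- nrow(dY)
    pb <- tn_pw_bwd(cache$attn_in, rbind(ab$dQ, ab$dK, ab$dV),
                    rbind(bp$pq$W, bp$pk$W, bp$pv$W))
    g$pq$W <- pb$dW[seq_len(C), , drop = FALSE]
    g$pk$W <- pb$dW[C + seq_len(C), , drop = FALSE]
    g$pv$W <- pb$dW[2L * C + seq_len(C), , drop = FALSE]
    g$pq$b <- as.numeric(pb$db)[seq_len(C)]
    g$pk$b <- as.numeric(pb$db)[C + seq_len(C)]
    g$pv$b <- as.numeric(pb$db)[2L * C + seq_len(C)]
    dXi3 <- dXi3 + pb$dX
  } else {
    dXi3 <- dY
  }
  dX0 <- if (spec$use_residual) dXi3 else matrix(0, nrow(dXi3), ncol(dXi3))
  dcur <- dXi3
  if (spec$use_conv) {
    sb <- tn_spat_attn_bwd(cache$sa_in, dcur, bp$sa$W, cache$sa$g, cache$sa$m,
                           H, W, B)
    g$sa$W <- sb$dW; g$sa$b <- as.numeric(sb$db)
    cb <- tn_chan_attn_bwd(cache$ca_in, sb$dX, bp$ca$w, cache$ca$P, cache$ca$S,
                           H, W, B)
    g$ca$w <- as.numeric(cb$dw)
    dcur <- cb$dX
    if (spec$directions != "time_only") {
      if (use_bn) {
        bb <- tn_bn_bwd(dcur, cache$bn_s$xhat, cache$bn_s$invstd,
                        bp$bn_s$gamma, cache$bn_s$Y, TRUE)
        g$bn_s$gamma <- as.numeric(bb$dgamma); g$bn_s$beta <- as.numeric(bb$dbeta)
        dcur <- bb$dX
      }
      sb2 <- tn_strip_bwd(cache$cs_in, dcur, bp$conv_s$W, H, W, B, FALSE)
      g$conv_s$W <- sb2$dW; g$conv_s$b <- as.numeric(sb2$db)
      dcur <- sb2$dX
    }
    if (spec$directions != "space_only") {
      if (use_bn) {
        bb <- tn_bn_bwd(dcur, cache$bn_t$xhat, cache$bn_t$invstd,
                        bp$bn_t$gamma, cache$bn_t$Y, TRUE)
        g$bn_t$gamma <- as.numeric(bb$dgamma); g$bn_t$beta <- as.numeric(bb$dbeta)
        dcur <- bb$dX
      }
      tb <- tn_strip_bwd(cache$ct_in, dcur, bp$conv_t$W, H, W, B, TRUE)
      g$conv_t$W <- tb$dW; g$conv_t$b <- as.numeric(tb$db)
      dcur <- tb$dX
    }
    dX <- dX0 + dcur
  } else {
    dX <- dX0 + dcur
  }
  list(dX = dX, g = g)
}

# ---- block forward/backward -------------------------------------------------

block_fwd <- function(X, blk, specs, H, W, B, training, use_bn) {
  outs <- vector("list", length(specs))
  caches <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    r <- branch_fwd(X, blk$branches[[i]], specs[[i]], H, W, B, training, use_bn)
    outs[[i]] <- r$Y
    caches[[i]] <- r$cache
    blk$branches[[i]] <- r$bp
  }
  Ycat <- do.call(rbind, outs)
  Xo <- tn_pw_fwd(Ycat, blk$fuse$W, blk$fuse$b)
  list(Y = Xo, cache = list(branches = caches, Ycat = Ycat), blk = blk)
}

block_bwd <- function(dXo, cache, blk, specs, H, W, B, use_bn) {
  g <- zero_like_tree(blk)
  fb <- tn_pw_bwd(cache$Ycat, dXo, blk$fuse$W)
  g$fuse$W <- fb$dW; g$fuse$b <- as.numeric(fb$db)
  C <- nrow(fb$dX) / length(specs)
  dX <- NULL
  for (i in seq_along(specs)) {
    rows <- ((i - 1) * C + 1):(i * C)
    rb <- branch_bwd(fb$dX[rows, , drop = FALSE], cache$branches[[i]],
                     blk$branches[[i]], specs[[i]], H, W, B, use_bn)
    g$branches[[i]] <- rb$g
    dX <- if (is.null(dX)) rb$dX else dX + rb$dX
  }
  list(dX = dX, g = g)
}

# ---- full model forward/backward -------------------------------------------

model_fwd <- function(params, config, Xin, H, W, B, training) {
  use_bn <- !config$strict_paper_mode
  specs <- config$branches
  cache <- list()
  X <- tn_pw_fwd(Xin, params$expand$W, params$expand$b)
  cache$expand_in <- Xin
  cache$blocks <- vector("list", length(params$blocks))
  cache$block_in <- vector("list", length(params$blocks))
  for (nb in seq_along(params$blocks)) {
    cache$block_in[[nb]] <- X
    r <- block_fwd(X, params$blocks[[nb]], specs, H, W, B, training, use_bn)
    cache$blocks[[nb]] <- r$cache
    params$blocks[[nb]] <- r$blk
    X <- r$Y
  }
  cache$reduce_in <- X
  R <- tn_pw_fwd(X, params$reduce$W, params$reduce$b)
  pmode <- if (config$pool_mode == "avg") 0L else 1L
  pr <- tn_pool2_fwd(R, H, W, B, pmode)
  cache$pool <- pr
  W2 <- W %/% 2L
  Fm <- matrix(as.vector(pr$Y), nrow = config$reduction_channels * H * W2)
  cache$Fm <- Fm
  A1 <- params$fc1$W %*% Fm + params$fc1$b
  cache$A1 <- A1
  Z1 <- pmax(A1, 0)
  cache$Z1 <- Z1
  logits <- params$fc2$W %*% Z1 + params$fc2$b
  list(logits = logits, cache = cache, params = params,
       geom = list(H = H, W = W, B = B))
}

model_bwd <- function(dlogits, fw, config) {
  params <- fw$params
  cache <- fw$cache
  H <- fw$geom$H; W <- fw$geom$W; B <- fw$geom$B
  use_bn <- !config$strict_paper_mode
  specs <- config$branches
  g <- zero_like_tree(params)
  g$fc2$W <- dlogits %*% t(cache$Z1)
  g$fc2$b <- as.numeric(rowSums(dlogits))
  dZ1 <- t(params$fc2$W) %*% dlogits
  dA1 <- dZ1 * (cache$A1 > 0)
  g$fc1$W <- dA1 %*% t(cache$Fm)
  g$fc1$b <- as.numeric(rowSums(dA1))
  dFm <- t(params$fc1$W) %*% dA1
  W2 <- W %/% 2L
  dpool <- matrix(as.vector(dFm), nrow = config$reduction_channels)
  pmode <- if (config$pool_mode == "avg") 0L else 1L
  dR <- tn_pool2_bwd(dpool, H, W, B, pmode, cache$pool$amax)
  rb <- tn_pw_bwd(cache$reduce_in, dR, params$reduce$W)
  g$reduce$W <- rb$dW; g$reduce$b <- as.numeric(rb$db)
  dX <- rb$dX
  for (nb in rev(seq_along(params$blocks))) {
    bb <- block_bwd(dX, cache$blocks[[nb]], params$blocks[[nb]], specs,
                    H, W, B, use_bn)
    g$blocks[[nb]] <- bb$g
    dX <- bb$dX
  }
  eb <- tn_pw_bwd(cache$expand_in, dX, params$expand$W)
  g$expand$W <- eb$dW; g$expand$b <- as.numeric(eb$db)
  g
}

# ---- loss and optimiser -----------------------------------------------------

# Softmax cross-entropy.  logits: K x B, y: integer class index 1..K.
softmax_xent <- function(logits, y) {
  K <- nrow(logits); B <- ncol(logits)
  shifted <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(shifted)
  p <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(y, seq_len(B))
  pidx <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(pidx, 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  list(loss = loss, dlogits = dlogits, prob = p)
}

softmax_cols <- function(logits) {
  shifted <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(shifted)
  sweep(e, 2, colSums(e), "/")
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(x) x * 0),
       v = lapply(fl, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(fp)) {
    if (is_buffer_name(nm)) next
    gi <- fg[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gi * gi
    fp[[nm]] <- fp[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = assign_flat(params, fp), state = state)
}

# Convert an H x W x B epoch array (or H x W matrix) to the engine layout
# (1 x H*W*B) and remember geometry.
epochs_to_engine <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  list(X = matrix(as.vector(x), nrow = 1L), H = d[1], W = d[2], B = d[3])
}
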