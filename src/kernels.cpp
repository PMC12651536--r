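// Compiled forward/backward kernels for the strip-convolution attention block.
//
// Feature maps travel through the engine as an arma::mat of size
// C x (H*W*B): one column per spatial position of one sample, column index
// j = h + H*(w + W*b) (0-based), i.e. electrode-major, time-minor, sample-
// slowest.  All kernels preserve that layout.  Strip convolutions use true
// convolution semantics (kernel flipped, matching the discrete double-sum
// definition used by the R-level oracle), with symmetric zero padding so H
// and W never change.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Shifted copy along the electrode axis: Xs[:, (h,w,b)] = X[:, (h+d,w,b)],
// out-of-range rows of the map are zero.  Used by the k x 1 strip factor,
// where the shift is not contiguous across the full sample block.
static void shift_space(const arma::mat& X, arma::mat& Xs, int H, int W,
                        int B, int d) {
  int lo = std::max(0, -d), hi = H - 1 - std::max(0, d);
  for (int b = 0; b < B; ++b) {
    for (int w = 0; w < W; ++w) {
      arma::uword base = ((arma::uword)b * W + w) * H;
      if (lo > 0) Xs.cols(base, base + lo - 1).zeros();
      if (hi >= lo)
        Xs.cols(base + lo, base + hi) = X.cols(base + lo + d, base + hi + d);
      if (hi < H - 1) Xs.cols(base + hi + 1, base + H - 1).zeros();
    }
  }
}

// Strip convolution forward: kernel cube Wk is C_out x C_in x k, traversing
// the time axis (1 x k) or the electrode axis (k x 1).  True convolution:
// slice n carries kernel coefficient y(n), applied at source offset
// u = p - n.
// [[Rcpp::export]]
arma::mat tn_strip_fwd(const arma::mat& X, const arma::cube& Wk,
                       const arma::vec& bias, int H, int W, int B,
                       bool time_dir) {
  int k = Wk.n_slices, p = (k - 1) / 2;
  arma::mat Y(Wk.n_rows, X.n_cols, arma::fill::zeros);
  arma::mat Xs;
  if (!time_dir) Xs.set_size(X.n_rows, X.n_cols);
  for (int n = 0; n < k; ++n) {
    int u = p - n;
    if (time_dir) {
      int lo = std::max(0, -u), hi = W - 1 - std::max(0, u);
      if (hi < lo) continue;
      for (int b = 0; b < B; ++b) {
        arma::uword base = (arma::uword)b * H * W;
        Y.cols(base + lo * H, base + (hi + 1) * H - 1) +=
            Wk.slice(n) * X.cols(base + (lo + u) * H, base + (hi + 1 + u) * H - 1);
      }
    } else {
      shift_space(X, Xs, H, W, B, u);
      Y += Wk.slice(n) * Xs;
    }
  }
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
List tn_strip_bwd(const arma::mat& X, const arma::mat& dY,
                  const arma::cube& Wk, int H, int W, int B, bool time_dir) {
  int k = Wk.n_slices, p = (k - 1) / 2;
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  arma::cube dW(Wk.n_rows, Wk.n_cols, k, arma::fill::zeros);
  arma::mat Xs, Ws;
  if (!time_dir) Xs.set_size(X.n_rows, X.n_cols);
  for (int n = 0; n < k; ++n) {
    int u = p - n;
    if (time_dir) {
      int lo = std::max(0, -u), hi = W - 1 - std::max(0, u);
      if (hi < lo) continue;
      arma::mat Wt = Wk.slice(n).t();
      for (int b = 0; b < B; ++b) {
        arma::uword base = (arma::uword)b * H * W;
        arma::uword d0 = base + lo * H, d1 = base + (hi + 1) * H - 1;
        arma::uword s0 = base + (lo + u) * H, s1 = base + (hi + 1 + u) * H - 1;
        dW.slice(n) += dY.cols(d0, d1) * X.cols(s0, s1).t();
        dX.cols(s0, s1) += Wt * dY.cols(d0, d1);
      }
    } else {
      shift_space(X, Xs, H, W, B, u);
      dW.slice(n) = dY * Xs.t();
      // scatter W^T dY back with the opposite shift
      arma::mat T = Wk.slice(n).t() * dY;
      shift_space(T, Xs, H, W, B, -u);
      dX += Xs;
    }
  }
  arma::vec db = arma::sum(dY, 1);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Point-wise (1x1) convolution: plain channel mixing.
// [[Rcpp::export]]
arma::mat tn_pw_fwd(const arma::mat& X, const arma::mat& W,
                    const arma::vec& bias) {
  arma::mat Y = W * X;
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
List tn_pw_bwd(const arma::mat& X, const arma::mat& dY, const arma::mat& W) {
  return List::create(_["dX"] = W.t() * dY, _["dW"] = dY * X.t(),
                      _["db"] = arma::vec(arma::sum(dY, 1)));
}

// Batch normalisation over channels (statistics across all positions and
// samples), optionally fused with a ReLU.  Single pass for the moments,
// single pass for the normalisation.  Returns activations, the normalised
// cache and updated running moments.
// [[Rcpp::export]]
List tn_bn_fwd(const arma::mat& X, const arma::vec& gamma,
               const arma::vec& beta, const arma::vec& rmean,
               const arma::vec& rvar, double momentum, bool training,
               double eps, bool relu) {
  int C = X.n_rows;
  arma::uword N = X.n_cols;
  arma::vec mu(C), va(C);
  if (training) {
    arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    const double* xp = X.memptr();
    for (arma::uword j = 0; j < N; ++j) {
      for (int c = 0; c < C; ++c) {
        double v = xp[j * C + c];
        s1(c) += v;
        s2(c) += v * v;
      }
    }
    mu = s1 / (double)N;
    va = s2 / (double)N - mu % mu;
    va.transform([](double v) { return v < 0 ? 0 : v; });
  } else {
    mu = rmean;
    va = rvar;
  }
  arma::vec invstd = 1.0 / arma::sqrt(va + eps);
  arma::mat xhat(C, N), Y(C, N);
  const double* xp = X.memptr();
  double* hp = xhat.memptr();
  double* yp = Y.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    for (int c = 0; c < C; ++c) {
      double h = (xp[j * C + c] - mu(c)) * invstd(c);
      hp[j * C + c] = h;
      double y = gamma(c) * h + beta(c);
      yp[j * C + c] = relu ? (y > 0 ? y : 0) : y;
    }
  }
  arma::vec nm = rmean, nv = rvar;
  if (training) {
    nm = (1 - momentum) * rmean + momentum * mu;
    nv = (1 - momentum) * rvar + momentum * va;
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = nm, _["rvar"] = nv);
}

// Backward of (optionally ReLU-fused) batch normalisation.  Y is the stored
// forward output (used only for the ReLU mask).
// [[Rcpp::export]]
List tn_bn_bwd(const arma::mat& dY_in, const arma::mat& xhat,
               const arma::vec& invstd, const arma::vec& gamma,
               const arma::mat& Y, bool relu) {
  int C = xhat.n_rows;
  arma::uword N = xhat.n_cols;
  arma::vec m1(C, arma::fill::zeros), m2(C, arma::fill::zeros),
      dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  const double* dp = dY_in.memptr();
  const double* hp = xhat.memptr();
  const double* yp = Y.memptr();
  arma::mat dxh(C, N);
  double* xp = dxh.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    for (int c = 0; c < C; ++c) {
      arma::uword ix = j * C + c;
      double d = dp[ix];
      if (relu && yp[ix] <= 0) d = 0;
      dbeta(c) += d;
      dgamma(c) += d * hp[ix];
      xp[ix] = d * gamma(c);
    }
  }
  // m1 = mean(dxhat), m2 = mean(dxhat * xhat) per channel
  for (int c = 0; c < C; ++c) {
    m1(c) = (dbeta(c) * gamma(c)) / (double)N;
    m2(c) = (dgamma(c) * gamma(c)) / (double)N;
  }
  arma::mat dX(C, N);
  double* op = dX.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    for (int c = 0; c < C; ++c) {
      arma::uword ix = j * C + c;
      op[ix] = (xp[ix] - m1(c) - hp[ix] * m2(c)) * invstd(c);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat tn_relu_fwd(const arma::mat& X) {
  return arma::clamp(X, 0.0, arma::datum::inf);
}

// [[Rcpp::export]]
arma::mat tn_relu_bwd(const arma::mat& dY, const arma::mat& Y) {
  return dY % arma::conv_to<arma::mat>::from(Y > 0);
}

// Channel attention gate: per-sample global average pool -> length-3 1-D
// convolution along the channel axis (single shared bias-free filter, zero
// padding 1) -> sigmoid -> per-channel rescaling.
// [[Rcpp::export]]
List tn_chan_attn_fwd(const arma::mat& X, const arma::vec& wca, int H, int W,
                      int B) {
  int C = X.n_rows;
  arma::uword HW = (arma::uword)H * W;
  arma::mat P(C, B), Q(C, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    P.col(b) = arma::mean(X.cols(b * HW, (b + 1) * HW - 1), 1);
  for (int u = -1; u <= 1; ++u) {
    double wu = wca(u + 1);
    for (int c = 0; c < C; ++c) {
      int src = c + u;
      if (src >= 0 && src < C) Q.row(c) += wu * P.row(src);
    }
  }
  arma::mat S = 1.0 / (1.0 + arma::exp(-Q));
  arma::mat Y = X;
  for (int b = 0; b < B; ++b)
    Y.cols(b * HW, (b + 1) * HW - 1).each_col() %= S.col(b);
  return List::create(_["Y"] = Y, _["P"] = P, _["S"] = S);
}

// [[Rcpp::export]]
List tn_chan_attn_bwd(const arma::mat& X, const arma::mat& dY,
                      const arma::vec& wca, const arma::mat& P,
                      const arma::mat& S, int H, int W, int B) {
  int C = X.n_rows;
  arma::uword HW = (arma::uword)H * W;
  arma::mat dX = dY, dS(C, B);
  for (int b = 0; b < B; ++b) {
    arma::span cs(b * HW, (b + 1) * HW - 1);
    dS.col(b) = arma::sum(dY.cols(cs) % X.cols(cs), 1);
    dX.cols(cs).each_col() %= S.col(b);
  }
  arma::mat dQ = dS % S % (1.0 - S);
  arma::vec dw(3, arma::fill::zeros);
  arma::mat dP(C, B, arma::fill::zeros);
  for (int u = -1; u <= 1; ++u) {
    for (int c = 0; c < C; ++c) {
      int src = c + u;
      if (src >= 0 && src < C) {
        dw(u + 1) += arma::dot(dQ.row(c), P.row(src));
        dP.row(src) += wca(u + 1) * dQ.row(c);
      }
    }
  }
  dP /= (double)HW;
  for (int b = 0; b < B; ++b)
    dX.cols(b * HW, (b + 1) * HW - 1).each_col() += dP.col(b);
  return List::create(_["dX"] = dX, _["dw"] = dw);
}

// 3x3 same (true) convolution of per-sample H x W maps stored as one
// column-stacked vector (h fastest); zero padding 1.
static arma::vec conv3x3_map(const arma::vec& g, const arma::mat& W9, int H,
                             int W, int B, bool transpose) {
  arma::vec out(g.n_elem, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::uword base = (arma::uword)b * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int n2 = 0; n2 < 3; ++n2) {
          int uw = 1 - n2;
          int ws = w + (transpose ? -uw : uw);
          if (ws < 0 || ws >= W) continue;
          for (int n1 = 0; n1 < 3; ++n1) {
            int uh = 1 - n1;
            int hs = h + (transpose ? -uh : uh);
            if (hs < 0 || hs >= H) continue;
            acc += W9(n1, n2) * g(base + ws * H + hs);
          }
        }
        out(base + w * H + h) = acc;
      }
    }
  }
  return out;
}

// Spatial attention gate: channel mean -> 3x3 convolution (+bias) -> sigmoid
// -> per-position rescaling.
// [[Rcpp::export]]
List tn_spat_attn_fwd(const arma::mat& X, const arma::mat& Wsa, double b0,
                      int H, int W, int B) {
  arma::vec g = arma::mean(X, 0).t();
  arma::vec q = conv3x3_map(g, Wsa, H, W, B, false) + b0;
  arma::vec m = 1.0 / (1.0 + arma::exp(-q));
  arma::mat Y = X;
  Y.each_row() %= m.t();
  return List::create(_["Y"] = Y, _["g"] = g, _["m"] = m);
}

// [[Rcpp::export]]
List tn_spat_attn_bwd(const arma::mat& X, const arma::mat& dY,
                      const arma::mat& Wsa, const arma::vec& g,
                      const arma::vec& m, int H, int W, int B) {
  int C = X.n_rows;
  arma::vec dm = arma::sum(dY % X, 0).t();
  arma::mat dX = dY;
  dX.each_row() %= m.t();
  arma::vec dq = dm % m % (1.0 - m);
  // one pass accumulating dW(n1,n2) = sum_j dq(j) g(j @ offset(n1,n2))
  arma::mat dW(3, 3, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::uword base = (arma::uword)b * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double d = dq(base + w * H + h);
        if (d == 0) continue;
        for (int n2 = 0; n2 < 3; ++n2) {
          int ws = w + 1 - n2;
          if (ws < 0 || ws >= W) continue;
          for (int n1 = 0; n1 < 3; ++n1) {
            int hs = h + 1 - n1;
            if (hs < 0 || hs >= H) continue;
            dW(n1, n2) += d * g(base + ws * H + hs);
          }
        }
      }
    }
  }
  double db = arma::accu(dq);
  arma::vec dg = conv3x3_map(dq, Wsa, H, W, B, true);
  dg /= (double)C;
  dX.each_row() += dg.t();
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Scaled dot-product self-attention over C channel tokens of length H*W,
// applied independently per sample.  Returns Z and the softmax matrices.
// [[Rcpp::export]]
List tn_attn_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 int H, int W, int B) {
  int C = Q.n_rows;
  arma::uword HW = (arma::uword)H * W;
  double scale = 1.0 / std::sqrt((double)HW);
  arma::mat Z(C, Q.n_cols);
  arma::cube Pc(C, C, B);
  for (int b = 0; b < B; ++b) {
    arma::span cs(b * HW, (b + 1) * HW - 1);
    arma::mat A = Q.cols(cs) * K.cols(cs).t() * scale;
    A.each_col() -= arma::max(A, 1);
    arma::mat P = arma::exp(A);
    P.each_col() /= arma::sum(P, 1);
    Pc.slice(b) = P;
    Z.cols(cs) = P * V.cols(cs);
  }
  return List::create(_["Z"] = Z, _["P"] = Pc);
}

// [[Rcpp::export]]
List tn_attn_bwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                 const arma::cube& Pc, const arma::mat& dZ, int H, int W,
                 int B) {
  arma::uword HW = (arma::uword)H * W;
  double scale = 1.0 / std::sqrt((double)HW);
  arma::mat dQ(arma::size(Q)), dK(arma::size(K)), dV(arma::size(V));
  for (int b = 0; b < B; ++b) {
    arma::span cs(b * HW, (b + 1) * HW - 1);
    const arma::mat& P = Pc.slice(b);
    dV.cols(cs) = P.t() * dZ.cols(cs);
    arma::mat dP = dZ.cols(cs) * V.cols(cs).t();
    arma::vec rs = arma::sum(dP % P, 1);
    arma::mat dA = P % (dP.each_col() - rs);
    dQ.cols(cs) = dA * K.cols(cs) * scale;
    dK.cols(cs) = dA.t() * Q.cols(cs) * scale;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Non-overlapping 1x2 pooling along the time axis; W -> floor(W/2).
// mode 0 = average, 1 = max.
// [[Rcpp::export]]
List tn_pool2_fwd(const arma::mat& X, int H, int W, int B, int mode) {
  int C = X.n_rows, W2 = W / 2;
  arma::mat Y(C, (arma::uword)H * W2 * B);
  arma::umat amax(mode == 1 ? C : 1, mode == 1 ? Y.n_cols : 1);
  for (int b = 0; b < B; ++b) {
    for (int w2 = 0; w2 < W2; ++w2) {
      arma::uword s0 = ((arma::uword)b * W + 2 * w2) * H;
      arma::uword s1 = s0 + H;
      arma::uword d0 = ((arma::uword)b * W2 + w2) * H;
      for (int h = 0; h < H; ++h) {
        for (int c = 0; c < C; ++c) {
          double a = X(c, s0 + h), bb = X(c, s1 + h);
          if (mode == 0) {
            Y(c, d0 + h) = 0.5 * (a + bb);
          } else {
            Y(c, d0 + h) = std::max(a, bb);
            amax(c, d0 + h) = (a >= bb) ? 0 : 1;
          }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat tn_pool2_bwd(const arma::mat& dY, int H, int W, int B, int mode,
                       const arma::umat& amax) {
  int C = dY.n_rows, W2 = W / 2;
  arma::mat dX(C, (arma::uword)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int w2 = 0; w2 < W2; ++w2) {
      arma::uword s0 = ((arma::uword)b * W + 2 * w2) * H;
      arma::uword s1 = s0 + H;
      arma::uword d0 = ((arma::uword)b * W2 + w2) * H;
      for (int h = 0; h < H; ++h) {
        for (int c = 0; c < C; ++c) {
          double g = dY(c, d0 + h);
          if (mode == 0) {
            dX(c, s0 + h) += 0.5 * g;
            dX(c, s1 + h) += 0.5 * g;
          } else {
            dX(c, (amax(c, d0 + h) == 0 ? s0 : s1) + h) += g;
          }
        }
      }
    }
  }
  return dX;
}
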