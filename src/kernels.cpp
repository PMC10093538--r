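// Hot numerical kernels for the CPU network engine: im2col/col2im-based
// 2-D convolution (forward, input-gradient, weight-gradient), direct
// depth-wise convolution, and same-padding max pooling with argmax.
//
// Tensor layout everywhere: an R numeric array dim (H, W, C), i.e. an
// arma::cube with H rows, W cols, C slices. Convolution weights are a
// matrix (C_out x k*k*C_in); row index packs (a, b, c) as a + k*b +
// k*k*c with a the kernel row offset, b the kernel col offset, c the
// input channel. Depth-wise weights are (k*k x C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(k * k * C, (size_t)Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int r = a + k * b + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + a;
            if (ii < 0 || ii >= H) continue;
            col(r, (size_t)i + (size_t)Ho * j) = xs(ii, jj);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_acc(cube& gx, const mat& gcol, int k, int stride,
                       int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& gs = gx.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int r = a + k * b + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + a;
            if (ii < 0 || ii >= H) continue;
            gs(ii, jj) += gcol(r, (size_t)i + (size_t)Ho * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          int k, int stride, int pad,
                          Rcpp::Nullable<Rcpp::NumericVector> bias) {
  const int Ho = (x.n_rows + 2 * pad - k) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - k) / stride + 1;
  const int Co = w.n_rows;
  cube out(Ho, Wo, Co);
  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise conv: a single GEMM on the (H*W x C) views
    const mat xm(const_cast<double*>(x.memptr()),
                 (size_t)Ho * Wo, x.n_slices, false, true);
    mat ym(out.memptr(), (size_t)Ho * Wo, Co, false, true);
    ym = xm * w.t();
  } else {
    mat col = im2col(x, k, stride, pad, Ho, Wo);
    mat y = w * col;                     // (Co x Ho*Wo)
    for (int c = 0; c < Co; ++c) {
      out.slice(c) = reshape(y.row(c), Ho, Wo);
    }
  }
  if (bias.isNotNull()) {
    Rcpp::NumericVector b(bias);
    for (int c = 0; c < Co; ++c) out.slice(c) += b[c];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int k, int stride,
                          int pad, bool has_bias) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  Rcpp::List out;
  if (k == 1 && stride == 1 && pad == 0) {
    const mat xm(const_cast<double*>(x.memptr()),
                 (size_t)Ho * Wo, x.n_slices, false, true);
    const mat gym(const_cast<double*>(gy.memptr()),
                  (size_t)Ho * Wo, Co, false, true);
    mat gw = gym.t() * xm;               // (Co x Cin)
    cube gx(x.n_rows, x.n_cols, x.n_slices);
    mat gxm(gx.memptr(), (size_t)Ho * Wo, x.n_slices, false, true);
    gxm = gym * w;
    out = Rcpp::List::create(Rcpp::Named("gx") = gx,
                             Rcpp::Named("gw") = gw);
    if (has_bias) {
      vec gb = sum(gym, 0).t();
      out["gb"] = Rcpp::NumericVector(gb.begin(), gb.end());
    }
  } else {
    mat gym(Co, (size_t)Ho * Wo);
    for (int c = 0; c < Co; ++c) {
      gym.row(c) = vectorise(gy.slice(c)).t();
    }
    mat col = im2col(x, k, stride, pad, Ho, Wo);
    mat gw = gym * col.t();
    mat gcol = w.t() * gym;
    cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
    col2im_acc(gx, gcol, k, stride, pad, Ho, Wo);
    out = Rcpp::List::create(Rcpp::Named("gx") = gx,
                             Rcpp::Named("gw") = gw);
    if (has_bias) {
      vec gb = sum(gym, 1);
      out["gb"] = Rcpp::NumericVector(gb.begin(), gb.end());
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_dwconv_fwd(const arma::cube& x, const arma::mat& w,
                          int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube y(Ho, Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    mat& ys = y.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const double wv = w(a + k * b, c);
        if (wv == 0.0) continue;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + a;
            if (ii < 0 || ii >= H) continue;
            ys(i, j) += wv * xs(ii, jj);
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int k, int stride,
                          int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, W, C, fill::zeros);
  mat gw(k * k, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const mat& gys = gy.slice(c);
    mat& gxs = gx.slice(c);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const double wv = w(a + k * b, c);
        double acc = 0.0;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride - pad + a;
            if (ii < 0 || ii >= H) continue;
            const double g = gys(i, j);
            acc += g * xs(ii, jj);
            gxs(ii, jj) += g * wv;
          }
        }
        gw(a + k * b, c) = acc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw);
}

// stride-1 same-padding max pooling; returns pooled map and 1-based
// argmax linear index (within each channel's H*W plane)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x, int k, int stride,
                           int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector arg((size_t)Ho * Wo * C);
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    mat& ys = y.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int b = 0; b < k; ++b) {
          const int jj = j * stride - pad + b;
          if (jj < 0 || jj >= W) continue;
          for (int a = 0; a < k; ++a) {
            const int ii = i * stride - pad + a;
            if (ii < 0 || ii >= H) continue;
            const double v = xs(ii, jj);
            if (v > best) { best = v; bi = ii + H * jj; }
          }
        }
        ys(i, j) = best;
        arg[q + (size_t)i + (size_t)Ho * j] = bi + 1;
      }
    }
    q += (size_t)Ho * Wo;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& gy,
                           const Rcpp::IntegerVector& argmax,
                           int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    const mat& gys = gy.slice(c);
    double* gxp = gx.slice(c).memptr();
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        gxp[argmax[q++] - 1] += gys(i, j);
      }
    }
  }
  return gx;
}
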