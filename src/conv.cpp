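// Convolution / pooling / batch-norm kernels for the CNN layers.
// Feature arrays use the R layout (H, W, C, N), column-major.
// Conv weights are K x (C*kh*kw) matrices; the flattened kernel index is
// r = (c*kh + di)*kw + dj, matching im2col below. im2col gathers the whole
// batch into one matrix so each conv is a single large GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int OH, int OW, double* colp, size_t ld) {
  // writes a (C*kh*kw) x (OH*OW) block with leading dimension ld
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        size_t r = (size_t)(c * kh + di) * kw + dj;
        for (int ow = 0; ow < OW; ++ow) {
          int w = ow * stride - pad + dj;
          double* dst = colp + r + ld * ((size_t)OH * ow);
          if (w < 0 || w >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[ld * oh] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * w;
          for (int oh = 0; oh < OH; ++oh) {
            int h = oh * stride - pad + di;
            dst[ld * oh] = (h >= 0 && h < H) ? src[h] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const double* colp, size_t ld, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int OH, int OW, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int di = 0; di < kh; ++di) {
      for (int dj = 0; dj < kw; ++dj) {
        size_t r = (size_t)(c * kh + di) * kw + dj;
        for (int ow = 0; ow < OW; ++ow) {
          int w = ow * stride - pad + dj;
          if (w < 0 || w >= W) continue;
          const double* src = colp + r + ld * ((size_t)OH * ow);
          double* dst = xc + (size_t)H * w;
          for (int oh = 0; oh < OH; ++oh) {
            int h = oh * stride - pad + di;
            if (h >= 0 && h < H) dst[h] += src[ld * oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix w,
                                 Nullable<NumericVector> bias,
                                 int kh, int kw, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = w.nrow();
  int CKK = w.ncol();
  if (CKK != C * kh * kw) stop("conv weight shape does not match input channels");
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  size_t P = (size_t)OH * OW;
  arma::mat Wm(w.begin(), K, CKK, false, true);
  NumericVector out(P * K * (size_t)N);
  arma::mat cols(CKK, P * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C,
               kh, kw, stride, pad, OH, OW,
               cols.memptr() + (size_t)CKK * P * n, CKK);
  arma::mat Yt = Wm * cols;  // K x (P*N), one large GEMM per batch
  // scatter to (OH, OW, K, N): out[p + P*k + P*K*n] = Yt(k, n*P + p)
  for (int n = 0; n < N; ++n) {
    double* yp = out.begin() + (size_t)n * P * K;
    const double* src = Yt.memptr() + (size_t)n * P * K;
    for (size_t p = 0; p < P; ++p)
      for (int k = 0; k < K; ++k)
        yp[p + P * k] = src[k + (size_t)K * p];
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n) {
      double* yp = out.begin() + (size_t)n * P * K;
      for (int k = 0; k < K; ++k) {
        double bk = b[k];
        double* col = yp + (size_t)k * P;
        for (size_t p = 0; p < P; ++p) col[p] += bk;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, K, N);
  return out;
}

// gather dy (OH,OW,K,N array) into a K x (P*N) matrix
static arma::mat gather_dy(const double* dy, size_t P, int K, int N) {
  arma::mat dYt(K, P * N);
  for (int n = 0; n < N; ++n) {
    const double* dp = dy + (size_t)n * P * K;
    double* dst = dYt.memptr() + (size_t)n * P * K;
    for (size_t p = 0; p < P; ++p)
      for (int k = 0; k < K; ++k)
        dst[k + (size_t)K * p] = dp[p + P * k];
  }
  return dYt;
}

// [[Rcpp::export]]
NumericVector conv2d_backward_input_cpp(NumericVector dy, IntegerVector xdim,
                                        NumericMatrix w,
                                        int kh, int kw, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = w.nrow();
  int CKK = w.ncol();
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  size_t P = (size_t)OH * OW;
  arma::mat Wm(w.begin(), K, CKK, false, true);
  NumericVector dx((size_t)H * W * C * N);  // zero-initialised
  arma::mat dYt = gather_dy(dy.begin(), P, K, N);
  arma::mat cols = Wm.t() * dYt;  // CKK x (P*N), one GEMM
  for (int n = 0; n < N; ++n)
    col2im_one(cols.memptr() + (size_t)CKK * P * n, CKK, H, W, C,
               kh, kw, stride, pad, OH, OW,
               dx.begin() + (size_t)n * H * W * C);
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
List conv2d_backward_weight_cpp(NumericVector dy, NumericVector x,
                                IntegerVector xdim, int K,
                                int kh, int kw, int stride, int pad,
                                bool with_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int CKK = C * kh * kw;
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  size_t P = (size_t)OH * OW;
  NumericMatrix dw(K, CKK);
  arma::mat dWm(dw.begin(), K, CKK, false, true);
  arma::vec db(K, arma::fill::zeros);
  arma::mat cols(CKK, P * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C,
               kh, kw, stride, pad, OH, OW,
               cols.memptr() + (size_t)CKK * P * n, CKK);
  arma::mat dYt = gather_dy(dy.begin(), P, K, N);
  dWm = dYt * cols.t();  // one GEMM
  if (with_bias) db = arma::sum(dYt, 1);
  if (with_bias)
    return List::create(_["dw"] = dw, _["db"] = NumericVector(db.begin(), db.end()));
  return List::create(_["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  size_t P = (size_t)OH * OW;
  NumericVector out(P * C * (size_t)N);
  IntegerVector arg(P * C * (size_t)N);  // 0-based index into (H*W) plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* yc = out.begin() + ((size_t)n * C + c) * P;
      int* ac = arg.begin() + ((size_t)n * C + c) * P;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int dj = 0; dj < k; ++dj) {
            int w = ow * stride - pad + dj;
            if (w < 0 || w >= W) continue;
            for (int di = 0; di < k; ++di) {
              int h = oh * stride - pad + di;
              if (h < 0 || h >= H) continue;
              double v = xc[(size_t)h + (size_t)H * w];
              if (v > best) { best = v; besti = h + H * w; }
            }
          }
          yc[(size_t)oh + (size_t)OH * ow] = best;
          ac[(size_t)oh + (size_t)OH * ow] = besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector argmax,
                                   IntegerVector xdim, int OH, int OW) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t P = (size_t)OH * OW;
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* dyc = dy.begin() + ((size_t)n * C + c) * P;
      const int* ac = argmax.begin() + ((size_t)n * C + c) * P;
      for (size_t p = 0; p < P; ++p)
        if (ac[p] >= 0) dxc[ac[p]] += dyc[p];
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Batch norm, training mode: computes per-channel batch statistics over
// (H, W, N), normalises, and returns y plus the caches needed backward.
// [[Rcpp::export]]
List bn_forward_train_cpp(NumericVector x, IntegerVector xdim,
                          NumericVector gamma, NumericVector beta,
                          double eps) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t HW = (size_t)H * W;
  double M = (double)HW * N;
  NumericVector mean(C), var(C), ivar(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double mu = s / M;
    double v = s2 / M - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v;
    ivar[c] = 1.0 / std::sqrt(v + eps);
  }
  NumericVector y(x.size()), xhat(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double* yc = y.begin() + ((size_t)n * C + c) * HW;
      double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
      double mu = mean[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        double h = (xc[i] - mu) * iv;
        hc[i] = h;
        yc[i] = g * h + b;
      }
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["var"] = var, _["ivar"] = ivar);
}

// Batch norm, inference mode: y = gamma*(x-mean)/sqrt(var+eps)+beta with
// supplied (running) statistics.
// [[Rcpp::export]]
NumericVector bn_forward_eval_cpp(NumericVector x, IntegerVector xdim,
                                  NumericVector gamma, NumericVector beta,
                                  NumericVector mean, NumericVector var,
                                  double eps) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double* yc = y.begin() + ((size_t)n * C + c) * HW;
      double iv = 1.0 / std::sqrt(var[c] + eps);
      double sc = gamma[c] * iv;
      double sh = beta[c] - mean[c] * sc;
      for (size_t i = 0; i < HW; ++i) yc[i] = xc[i] * sc + sh;
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat,
                     IntegerVector xdim, NumericVector gamma,
                     NumericVector ivar) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t HW = (size_t)H * W;
  double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + ((size_t)n * C + c) * HW;
      const double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
  }
  NumericVector dx(dy.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dc = dy.begin() + ((size_t)n * C + c) * HW;
      const double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
      double* xc = dx.begin() + ((size_t)n * C + c) * HW;
      double giv = gamma[c] * ivar[c];
      double s1 = dbeta[c] / M, s2 = dgamma[c] / M;
      for (size_t i = 0; i < HW; ++i)
        xc[i] = giv * (dc[i] - s1 - hc[i] * s2);
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// In-place rectifier. Every call site owns its input (a freshly allocated
// conv/BN output), so mutating it avoids a full copy.
// [[Rcpp::export]]
NumericVector relu_forward_cpp(NumericVector x) {
  for (R_xlen_t i = 0; i < x.size(); ++i) if (x[i] < 0) x[i] = 0.0;
  return x;
}

// Backward using the forward output as the gate (y > 0 <=> x > 0 a.e.).
// Mutates dy in place; the backward chain owns it.
// [[Rcpp::export]]
NumericVector relu_backward_cpp(NumericVector dy, NumericVector y) {
  for (R_xlen_t i = 0; i < dy.size(); ++i) if (y[i] <= 0) dy[i] = 0.0;
  return dy;
}

// y = relu(x + s), written into x in place (x is the fresh branch output).
// [[Rcpp::export]]
NumericVector add_relu_cpp(NumericVector x, NumericVector s) {
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i] + s[i];
    x[i] = v > 0 ? v : 0.0;
  }
  return x;
}

// Fill a (possibly huge) vector with N(0, sd) draws from R's RNG without
// allocating a second copy, so multi-gigabyte weight tensors initialise
// within memory budget.
// [[Rcpp::export]]
NumericVector fill_rnorm_cpp(NumericVector x, double sd) {
  RNGScope scope;
  for (R_xlen_t i = 0; i < x.size(); ++i) x[i] = norm_rand() * sd;
  return x;
}
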