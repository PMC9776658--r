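// Dense-tensor primitives for the four-stream network: valid-padding 2-D
// convolution over all input channels (im2col + GEMM), and max-pooling with
// cached argmax for the backward pass. Arrays use R's column-major layout
// (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void check_dims(const IntegerVector& d, int n, const char* what) {
  if (d.size() != n) stop("%s must be a %d-d array", what, n);
}

// x: (H,W,C,N); w: (kh,kw,C,F); b: length F. Valid padding, stride (sh,sw).
// Returns y: (Ho,Wo,F,N).
// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  check_dims(xd, 4, "x"); check_dims(wd, 4, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("kernel depth %d != input channels %d", (int)wd[2], C);
  if (b.size() != F) stop("bias length mismatch");
  const int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than input");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, F, false, true);
  NumericVector y((R_xlen_t)P * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  // one im2col matrix for the whole batch -> a single large GEMM
  arma::mat cols(K, (size_t)P * N);

  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    for (int oj = 0; oj < Wo; oj++) {
      for (int oi = 0; oi < Ho; oi++) {
        double* cp = cols.colptr((size_t)n * P + oi + (size_t)Ho * oj);
        for (int c = 0; c < C; c++) {
          const double* xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < kw; kj++) {
            const double* src = xc + (size_t)(oj * sw + kj) * H + oi * sh;
            double* dst = cp + kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ki++) dst[ki] = src[ki];
          }
        }
      }
    }
  }
  arma::mat out = cols.t() * Wm;  // (P*N) x F, spatial index fastest
  for (int n = 0; n < N; n++) {
    double* yn = y.begin() + (size_t)n * P * F;
    for (int f = 0; f < F; f++) {
      const double bf = b[f];
      const double* of = out.colptr(f) + (size_t)n * P;
      double* yf = yn + (size_t)P * f;
      for (int s = 0; s < P; s++) yf[s] = of[s] + bf;
    }
  }
  return y;
}

// Gradients of conv2d_forward. dy: (Ho,Wo,F,N). Returns dx, dw, db.
// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  check_dims(xd, 4, "x"); check_dims(wd, 4, "w"); check_dims(yd, 4, "dy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != F || yd[3] != N) stop("dy shape mismatch");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, F, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::vec db(F, arma::fill::zeros);
  // rebuild the batch im2col matrix (cheaper than caching it) and gather
  // dy as a (P*N) x F matrix so each gradient is one large GEMM
  arma::mat cols(K, (size_t)P * N);
  arma::mat dyM((size_t)P * N, F);
  for (int n = 0; n < N; n++) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * P * F;
    for (int f = 0; f < F; f++) {
      const double* df = dyn + (size_t)P * f;
      double* dst = dyM.colptr(f) + (size_t)n * P;
      double s = 0;
      for (int t = 0; t < P; t++) { dst[t] = df[t]; s += df[t]; }
      db[f] += s;
    }
    for (int oj = 0; oj < Wo; oj++) {
      for (int oi = 0; oi < Ho; oi++) {
        double* cp = cols.colptr((size_t)n * P + oi + (size_t)Ho * oj);
        for (int c = 0; c < C; c++) {
          const double* xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < kw; kj++) {
            const double* src = xc + (size_t)(oj * sw + kj) * H + oi * sh;
            double* dst = cp + kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ki++) dst[ki] = src[ki];
          }
        }
      }
    }
  }
  arma::mat dWm = cols * dyM;            // K x F
  arma::mat dcols = Wm * dyM.t();        // K x (P*N), contiguous per patch
  for (int n = 0; n < N; n++) {
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int oj = 0; oj < Wo; oj++) {
      for (int oi = 0; oi < Ho; oi++) {
        const double* cp = dcols.colptr((size_t)n * P + oi + (size_t)Ho * oj);
        for (int c = 0; c < C; c++) {
          double* xc = dxn + (size_t)c * H * W;
          for (int kj = 0; kj < kw; kj++) {
            double* dst = xc + (size_t)(oj * sw + kj) * H + oi * sh;
            const double* src = cp + kh * (kj + kw * c);
            for (int ki = 0; ki < kh; ki++) dst[ki] += src[ki];
          }
        }
      }
    }
  }
  NumericVector dwOut(w.size());
  dwOut.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dwOut.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwOut,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling, valid padding. Returns y (Ho,Wo,C,N) and the 0-based linear
// argmax index into x for every output element.
// [[Rcpp::export]]
List maxpool_forward(NumericVector x, int ph, int pw, int sh, int sw) {
  IntegerVector xd = x.attr("dim");
  check_dims(xd, 4, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H - ph) / sh + 1, Wo = (W - pw) / sw + 1;
  if (Ho < 1 || Wo < 1) stop("pool window larger than input");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());

  R_xlen_t t = 0;
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t plane = ((size_t)n * C + c) * H * W;
      const double* xp = x.begin() + plane;
      for (int oj = 0; oj < Wo; oj++) {
        for (int oi = 0; oi < Ho; oi++) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < pw; kj++) {
            const double* col = xp + (size_t)(oj * sw + kj) * H + oi * sh;
            for (int ki = 0; ki < ph; ki++) {
              if (col[ki] > best) {
                best = col[ki];
                besti = plane + (size_t)(oj * sw + kj) * H + oi * sh + ki;
              }
            }
          }
          // y index oi + Ho*(oj + Wo*(c + C*n)) — but we iterate (n,c,oj,oi)
          R_xlen_t yi = oi + (R_xlen_t)Ho * (oj + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          y[yi] = best;
          idx[yi] = (int)besti;
          t++;
        }
      }
    }
  }
  (void)t;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter pooled gradients back to the input positions.
// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); i++) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < dy.size(); t++) dx[idx[t]] += dy[t];
  return dx;
}

// Fused batchnorm + ReLU over channel dimension of (H,W,C,N) arrays.
// Training mode computes biased batch statistics and updates the running
// mean/variance with the given momentum; inference mode uses the running
// statistics. Returns the activated output plus the statistics needed for
// the backward pass.
// [[Rcpp::export]]
List bn_relu_forward(NumericVector x, NumericVector g, NumericVector B,
                     NumericVector run_mean, NumericVector run_var,
                     bool training, double momentum, double eps) {
  IntegerVector xd = x.attr("dim");
  check_dims(xd, 4, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector mean(C), invstd(C), new_rm(C), new_rv(C);

  if (training) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (int n = 0; n < N; n++) {
      for (int c = 0; c < C; c++) {
        const double* xp = x.begin() + ((size_t)n * C + c) * HW;
        double a = 0, b = 0;
        for (size_t t = 0; t < HW; t++) { a += xp[t]; b += xp[t] * xp[t]; }
        s1[c] += a; s2[c] += b;
      }
    }
    for (int c = 0; c < C; c++) {
      const double mu = s1[c] / m;
      const double v = s2[c] / m - mu * mu;
      mean[c] = mu;
      invstd[c] = 1.0 / std::sqrt(v + eps);
      new_rm[c] = momentum * run_mean[c] + (1 - momentum) * mu;
      new_rv[c] = momentum * run_var[c] + (1 - momentum) * v;
    }
  } else {
    for (int c = 0; c < C; c++) {
      mean[c] = run_mean[c];
      invstd[c] = 1.0 / std::sqrt(run_var[c] + eps);
      new_rm[c] = run_mean[c];
      new_rv[c] = run_var[c];
    }
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      double* yp = y.begin() + ((size_t)n * C + c) * HW;
      const double sc = g[c] * invstd[c];
      const double off = B[c] - mean[c] * sc;
      for (size_t t = 0; t < HW; t++) {
        const double v = xp[t] * sc + off;
        yp[t] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["run_mean"] = new_rm, _["run_var"] = new_rv);
}

// Backward of bn_relu_forward (training mode). x is the batchnorm input,
// y the activated output, dy the incoming gradient. Returns dx, dg, dB.
// [[Rcpp::export]]
List bn_relu_backward(NumericVector x, NumericVector y, NumericVector dy,
                      NumericVector mean, NumericVector invstd,
                      NumericVector g) {
  IntegerVector xd = x.attr("dim");
  check_dims(xd, 4, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;

  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xp = x.begin() + off;
      const double* yp = y.begin() + off;
      const double* dp = dy.begin() + off;
      const double mu = mean[c], is = invstd[c];
      double a = 0, b = 0;
      for (size_t t = 0; t < HW; t++) {
        if (yp[t] > 0) {
          const double d = dp[t];
          a += d;
          b += d * (xp[t] - mu) * is;
        }
      }
      s1[c] += a; s2[c] += b;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xp = x.begin() + off;
      const double* yp = y.begin() + off;
      const double* dp = dy.begin() + off;
      double* op = dx.begin() + off;
      const double mu = mean[c], is = invstd[c];
      const double k = g[c] * is / m;
      for (size_t t = 0; t < HW; t++) {
        const double d = yp[t] > 0 ? dp[t] : 0.0;
        const double xhat = (xp[t] - mu) * is;
        op[t] = k * (m * d - s1[c] - xhat * s2[c]);
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dg"] = NumericVector(s2.begin(), s2.end()),
                      _["dB"] = NumericVector(s1.begin(), s1.end()));
}
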