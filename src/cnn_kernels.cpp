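// Data-movement kernels for the spectrogram CNN. Activations are stored as
// matrices with rows indexing (h, w, n) -- h fastest, then w, then image --
// and one column per channel, so convolutions reduce to one BLAS matrix
// product per layer. These kernels implement the im2col gather, its
// scatter-add adjoint, 2x2 max pooling, and the (h,w,n)xC <-> Nx(h,w,c)
// flatten used at the fully connected interface.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3_nc(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int H2 = H - 2, W2 = W - 2;
  NumericMatrix out((R_xlen_t)H2 * W2 * N, 9 * C);
  const double* xp = X.begin();
  double* op = out.begin();
  const R_xlen_t xcolstride = (R_xlen_t)H * W * N;
  const R_xlen_t ocolstride = (R_xlen_t)H2 * W2 * N;
  for (int dh = 0; dh < 3; ++dh) {
    for (int dw = 0; dw < 3; ++dw) {
      const int blk = dh * 3 + dw;
      for (int c = 0; c < C; ++c) {
        const double* src = xp + xcolstride * c;
        double* dst = op + ocolstride * (blk * C + c);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W2; ++w) {
            const double* s = src + dh + (R_xlen_t)H * (dw + w + (R_xlen_t)W * n);
            double* d = dst + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * n);
            std::memcpy(d, s, sizeof(double) * H2);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im3_nc(const NumericMatrix& dM, int H, int W, int N, int C) {
  const int H2 = H - 2, W2 = W - 2;
  NumericMatrix out((R_xlen_t)H * W * N, C);
  const double* mp = dM.begin();
  double* op = out.begin();
  const R_xlen_t mcolstride = (R_xlen_t)H2 * W2 * N;
  const R_xlen_t ocolstride = (R_xlen_t)H * W * N;
  for (int dh = 0; dh < 3; ++dh) {
    for (int dw = 0; dw < 3; ++dw) {
      const int blk = dh * 3 + dw;
      for (int c = 0; c < C; ++c) {
        const double* src = mp + mcolstride * (blk * C + c);
        double* dst = op + ocolstride * c;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W2; ++w) {
            const double* s = src + (R_xlen_t)H2 * (w + (R_xlen_t)W2 * n);
            double* d = dst + dh + (R_xlen_t)H * (dw + w + (R_xlen_t)W * n);
            for (int h = 0; h < H2; ++h) d[h] += s[h];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List pool2_fwd_nc(const NumericMatrix& X, int H, int W, int N, int stride) {
  const int C = X.ncol();
  const int H3 = (H - 2) / stride + 1;
  const int W3 = (W - 2) / stride + 1;
  NumericMatrix out((R_xlen_t)H3 * W3 * N, C);
  IntegerMatrix which((R_xlen_t)H3 * W3 * N, C);
  const double* xp = X.begin();
  const R_xlen_t xcolstride = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    const double* src = xp + xcolstride * c;
    R_xlen_t o = 0;
    for (int n = 0; n < N; ++n) {
      const double* sn = src + (R_xlen_t)H * W * n;
      for (int w3 = 0; w3 < W3; ++w3) {
        const int w0 = w3 * stride;
        for (int h3 = 0; h3 < H3; ++h3, ++o) {
          const int h0 = h3 * stride;
          double best = sn[h0 + (R_xlen_t)H * w0];
          int arg = 0;
          const double v1 = sn[h0 + (R_xlen_t)H * (w0 + 1)];
          if (v1 > best) { best = v1; arg = 1; }
          const double v2 = sn[h0 + 1 + (R_xlen_t)H * w0];
          if (v2 > best) { best = v2; arg = 2; }
          const double v3 = sn[h0 + 1 + (R_xlen_t)H * (w0 + 1)];
          if (v3 > best) { best = v3; arg = 3; }
          out(o, c) = best;
          which(o, c) = arg;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericMatrix pool2_bwd_nc(const NumericMatrix& dOut, const IntegerMatrix& which,
                           int H, int W, int N, int stride) {
  const int C = dOut.ncol();
  const int H3 = (H - 2) / stride + 1;
  const int W3 = (W - 2) / stride + 1;
  NumericMatrix dX((R_xlen_t)H * W * N, C);
  double* xp = dX.begin();
  const R_xlen_t xcolstride = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    double* dst = xp + xcolstride * c;
    R_xlen_t o = 0;
    for (int n = 0; n < N; ++n) {
      double* dn = dst + (R_xlen_t)H * W * n;
      for (int w3 = 0; w3 < W3; ++w3) {
        const int w0 = w3 * stride;
        for (int h3 = 0; h3 < H3; ++h3, ++o) {
          const int h0 = h3 * stride;
          const int arg = which(o, c);
          const int dh = arg >> 1, dw = arg & 1;
          dn[h0 + dh + (R_xlen_t)H * (w0 + dw)] += dOut(o, c);
        }
      }
    }
  }
  return dX;
}

// (h,w,n) x C activation matrix -> N x (h,w,c) feature matrix
// [[Rcpp::export]]
NumericMatrix nc_to_flat(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  NumericMatrix out(N, (R_xlen_t)H * W * C);
  const double* xp = X.begin();
  for (int c = 0; c < C; ++c) {
    const double* src = xp + (R_xlen_t)H * W * N * c;
    for (int n = 0; n < N; ++n) {
      const double* s = src + (R_xlen_t)H * W * n;
      for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw)
        out(n, hw + (R_xlen_t)H * W * c) = s[hw];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix flat_to_nc(const NumericMatrix& F, int H, int W, int N, int C) {
  NumericMatrix out((R_xlen_t)H * W * N, C);
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    double* dst = op + (R_xlen_t)H * W * N * c;
    for (int n = 0; n < N; ++n) {
      double* d = dst + (R_xlen_t)H * W * n;
      for (R_xlen_t hw = 0; hw < (R_xlen_t)H * W; ++hw)
        d[hw] = F(n, hw + (R_xlen_t)H * W * c);
    }
  }
  return out;
}

// fused bias add + ReLU: max(Z + b[col], 0)
// [[Rcpp::export]]
NumericMatrix bias_relu_nc(const NumericMatrix& Z, const NumericVector& b) {
  const R_xlen_t m = Z.nrow();
  const int C = Z.ncol();
  NumericMatrix out(m, C);
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    const double* z = Z.begin() + m * c;
    double* o = out.begin() + m * c;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double v = z[i] + bc;
      o[i] = v > 0 ? v : 0;
    }
  }
  return out;
}

// fused batchnorm affine transform; returns the output and the
// standardized activations needed for the backward pass
// [[Rcpp::export]]
List bn_apply_nc(const NumericMatrix& X, const NumericVector& mu,
                 const NumericVector& invstd, const NumericVector& gamma,
                 const NumericVector& beta) {
  const R_xlen_t m = X.nrow();
  const int C = X.ncol();
  NumericMatrix out(m, C), xhat(m, C);
  for (int c = 0; c < C; ++c) {
    const double mc = mu[c], sc = invstd[c], gc = gamma[c], bc = beta[c];
    const double* x = X.begin() + m * c;
    double* o = out.begin() + m * c;
    double* xh = xhat.begin() + m * c;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double h = (x[i] - mc) * sc;
      xh[i] = h;
      o[i] = h * gc + bc;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// batchnorm backward: dX, dgamma, dbeta from upstream gradient
// [[Rcpp::export]]
List bn_bwd_nc(const NumericMatrix& dY, const NumericMatrix& xhat,
               const NumericVector& invstd, const NumericVector& gamma) {
  const R_xlen_t m = dY.nrow();
  const int C = dY.ncol();
  NumericMatrix dX(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.begin() + m * c;
    const double* xh = xhat.begin() + m * c;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double k = gamma[c] * invstd[c];
    const double a1 = sb / (double)m, a2 = sg / (double)m;
    double* dx = dX.begin() + m * c;
    for (R_xlen_t i = 0; i < m; ++i)
      dx[i] = k * (dy[i] - a1 - xh[i] * a2);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// column means and inverse standard deviations (biased variance), one pass
// [[Rcpp::export]]
List col_moments_nc(const NumericMatrix& X, double eps) {
  const R_xlen_t m = X.nrow();
  const int C = X.ncol();
  NumericVector mu(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.begin() + m * c;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < m; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    const double mc = s / (double)m;
    double v = s2 / (double)m - mc * mc;
    if (v < 0) v = 0;
    mu[c] = mc;
    var[c] = v;
    invstd[c] = 1.0 / std::sqrt(v + eps);
  }
  return List::create(_["mu"] = mu, _["var"] = var, _["invstd"] = invstd);
}

// elementwise product with the positive-part mask of a reference matrix:
// dZ = dA * (A > 0)
// [[Rcpp::export]]
NumericMatrix relu_mask_nc(const NumericMatrix& dA, const NumericMatrix& A) {
  const R_xlen_t n = dA.size();
  NumericMatrix out(dA.nrow(), dA.ncol());
  const double* da = dA.begin();
  const double* a = A.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i] > 0 ? da[i] : 0;
  return out;
}
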