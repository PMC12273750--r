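// Convolution memory-layout kernels: im2col / col2im and the
// (positions x channels) <-> feature-map permutations. Feature maps are
// column-major arrays (H, W, C, N); patch matrices have rows indexed by
// (out_row, out_col, sample) and column blocks of C channels per kernel
// offset, offsets ordered column-major (kj outer, ki inner).
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline int range_lo(int koff, int pad, int stride) {
  // smallest o with o*stride + koff - pad >= 0
  int lo = pad - koff;
  if (lo <= 0) return 0;
  return (lo + stride - 1) / stride;
}

static inline int range_hi(int koff, int pad, int stride, int n_in,
                           int n_out) {
  // largest o with o*stride + koff - pad <= n_in - 1
  const int num = n_in - 1 - koff + pad;
  if (num < 0) return -1;
  int hi = num / stride;
  return hi < n_out - 1 ? hi : n_out - 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad, int Ho, int Wo) {
  NumericMatrix P((R_xlen_t)Ho * Wo * N, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* Pp = P.begin();
  const size_t nrow = (size_t)Ho * Wo * N;
  const size_t plane = (size_t)H * W;
  for (int kj = 0; kj < k; ++kj) {
    const int oj_lo = range_lo(kj, pad, stride);
    const int oj_hi = range_hi(kj, pad, stride, W, Wo);
    for (int ki = 0; ki < k; ++ki) {
      const int b = kj * k + ki;
      const int oi_lo = range_lo(ki, pad, stride);
      const int oi_hi = range_hi(ki, pad, stride, H, Ho);
      const int len = oi_hi - oi_lo + 1;
      if (len <= 0) continue;
      for (int c = 0; c < C; ++c) {
        double* col = Pp + ((size_t)b * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + plane * (c + (size_t)C * n);
          double* dstn = col + (size_t)n * Ho * Wo;
          for (int oj = oj_lo; oj <= oj_hi; ++oj) {
            const int j = oj * stride + kj - pad;
            const double* src = xc + (size_t)j * H + oi_lo * stride +
                                ki - pad;
            double* dst = dstn + (size_t)oj * Ho + oi_lo;
            if (stride == 1) {
              std::memcpy(dst, src, len * sizeof(double));
            } else {
              for (int t = 0; t < len; ++t) dst[t] = src[t * stride];
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int H, int W, int C, int N,
                         int k, int stride, int pad, int Ho, int Wo) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* xp = dx.begin();
  const double* Pp = dP.begin();
  const size_t nrow = (size_t)Ho * Wo * N;
  const size_t plane = (size_t)H * W;
  for (int kj = 0; kj < k; ++kj) {
    const int oj_lo = range_lo(kj, pad, stride);
    const int oj_hi = range_hi(kj, pad, stride, W, Wo);
    for (int ki = 0; ki < k; ++ki) {
      const int b = kj * k + ki;
      const int oi_lo = range_lo(ki, pad, stride);
      const int oi_hi = range_hi(ki, pad, stride, H, Ho);
      const int len = oi_hi - oi_lo + 1;
      if (len <= 0) continue;
      for (int c = 0; c < C; ++c) {
        const double* col = Pp + ((size_t)b * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          double* xc = xp + plane * (c + (size_t)C * n);
          const double* srcn = col + (size_t)n * Ho * Wo;
          for (int oj = oj_lo; oj <= oj_hi; ++oj) {
            const int j = oj * stride + kj - pad;
            double* dst = xc + (size_t)j * H + oi_lo * stride + ki - pad;
            const double* src = srcn + (size_t)oj * Ho + oi_lo;
            for (int t = 0; t < len; ++t) dst[t * stride] += src[t];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_col2feat(NumericMatrix M, int Ho, int Wo, int N) {
  const int Cout = M.ncol();
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  const double* mp = M.begin();
  double* yp = y.begin();
  const size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < Cout; ++c) {
    const double* colp = mp + (size_t)c * plane * N;
    for (int n = 0; n < N; ++n)
      std::memcpy(yp + plane * (c + (size_t)Cout * n),
                  colp + plane * n, plane * sizeof(double));
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_feat2col(NumericVector y, int Ho, int Wo, int Cout,
                           int N) {
  NumericMatrix M((R_xlen_t)Ho * Wo * N, Cout);
  const double* yp = y.begin();
  double* mp = M.begin();
  const size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < Cout; ++c) {
    double* colp = mp + (size_t)c * plane * N;
    for (int n = 0; n < N; ++n)
      std::memcpy(colp + plane * n,
                  yp + plane * (c + (size_t)Cout * n),
                  plane * sizeof(double));
  }
  return M;
}
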