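// im2col / col2im packing for stride-1 2-D convolution over arrays laid
// out (C, H, W, N).  The arithmetic itself runs through BLAS at the R
// level (crossprod/tcrossprod on the packed matrix); these kernels only
// move memory.
//
// Packed layout: row r = ci + C*(ki + k*kj), column m = ho + Ho*(wo + Wo*n),
// matching the aperm(w, c(3, 1, 2, 4)) flattening of an
// (k, k, Cin, Cout) weight array.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k, int pad) {
  int d[4];
  get_dims(x, d);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const R_xlen_t M = static_cast<R_xlen_t>(Ho) * Wo * N;
  const int KK = C * k * k;
  NumericMatrix out(KK, M);
  const double* X = x.begin();
  double* O = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* col = O + KK * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kj = 0; kj < k; ++kj) {
          const int ws = wo + kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            const int hs = ho + ki - pad;
            double* dst = col + C * (ki + k * kj);
            if (ws < 0 || ws >= W || hs < 0 || hs >= H) {
              std::fill(dst, dst + C, 0.0);
            } else {
              const double* src =
                X + (R_xlen_t)C * (hs + (R_xlen_t)H * (ws + (R_xlen_t)W * n));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add packed columns back to the input shape (gradient of im2col).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int pad) {
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  const double* G = cols.begin();
  const int KK = C * k * k;
  double* DX = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* col =
          G + (R_xlen_t)KK * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kj = 0; kj < k; ++kj) {
          const int ws = wo + kj - pad;
          if (ws < 0 || ws >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hs = ho + ki - pad;
            if (hs < 0 || hs >= H) continue;
            const double* src = col + C * (ki + k * kj);
            double* dst =
              DX + (R_xlen_t)C * (hs + (R_xlen_t)H * (ws + (R_xlen_t)W * n));
            for (int ci = 0; ci < C; ++ci) dst[ci] += src[ci];
          }
        }
      }
    }
  }
  return dx;
}
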