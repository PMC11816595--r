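// im2col / col2im kernels for the convolution layers.
//
// Activations are H x W x N x C column-major arrays (linear index
// h + H*(w + W*(n + N*c))). im2col rows are indexed by (h, w, n); column
// blocks iterate kernel offsets (i fastest within j) with channels inside
// each block — the same ordering the R-side weight reshape uses.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t HWN = (R_xlen_t)H * W * N;
  NumericMatrix cols(HWN, (R_xlen_t)k * k * C);
  const double *px = x.begin();
  int blk = 0;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int di = i - p, dj = j - p;
      for (int c = 0; c < C; ++c) {
        double *dst = &cols(0, blk + c);
        for (int n = 0; n < N; ++n) {
          const R_xlen_t src_n = ((R_xlen_t)n + (R_xlen_t)N * c) * W;
          const R_xlen_t dst_n = (R_xlen_t)n * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            double *d = dst + ((dst_n + w) * H);
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h) d[h] = 0.0;
              continue;
            }
            const double *s = px + ((src_n + sw) * H);
            const int h0 = (di < 0) ? -di : 0;
            const int h1 = (di > 0) ? H - di : H;
            for (int h = 0; h < h0; ++h) d[h] = 0.0;
            for (int h = h0; h < h1; ++h) d[h] = s[h + di];
            for (int h = h1; h < H; ++h) d[h] = 0.0;
          }
        }
      }
      blk += C;
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int k) {
  const int p = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  double *po = out.begin();
  int blk = 0;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int di = i - p, dj = j - p;
      for (int c = 0; c < C; ++c) {
        const double *src = &cols(0, blk + c);
        for (int n = 0; n < N; ++n) {
          const R_xlen_t out_n = ((R_xlen_t)n + (R_xlen_t)N * c) * W;
          const R_xlen_t src_n = (R_xlen_t)n * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            if (sw < 0 || sw >= W) continue;
            const double *s = src + ((src_n + w) * H);
            double *d = po + ((out_n + sw) * H);
            const int h0 = (di < 0) ? -di : 0;
            const int h1 = (di > 0) ? H - di : H;
            for (int h = h0; h < h1; ++h) d[h + di] += s[h];
          }
        }
      }
      blk += C;
    }
  }
  return out;
}
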