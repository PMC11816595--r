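// Fused eval-mode forward pass for the folded backbone: every convolution
// (batch-norm already folded into W and b on the R side), ReLU, residual
// add, sigmoid channel attention, global average pooling and the softmax
// head in one call. The black-box query loop spends almost all of its time
// here, so the whole batch stays in C++.
//
// Activation layout matches the R side: column-major (H, W, N, C), i.e. a
// (H*W*N) x C matrix whose rows for sample n are the contiguous block
// [n*H*W, (n+1)*H*W).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col on an (H*W*N) x C activation matrix; column blocks ordered by
// kernel offset (i fastest within j), channels within each block — in
// lockstep with the R-side weight reshape conv_w2().
static arma::mat im2col_mat(const arma::mat &x, int H, int W, int N, int k) {
  const int C = x.n_cols;
  const int p = (k - 1) / 2;
  const arma::uword HWN = (arma::uword)H * W * N;
  arma::mat cols(HWN, (arma::uword)k * k * C);
  int blk = 0;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int di = i - p, dj = j - p;
      for (int c = 0; c < C; ++c) {
        const double *src = x.colptr(c);
        double *dst = cols.colptr(blk + c);
        for (int n = 0; n < N; ++n) {
          const arma::uword base = (arma::uword)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            double *d = dst + base + (arma::uword)w * H;
            if (sw < 0 || sw >= W) {
              std::fill(d, d + H, 0.0);
              continue;
            }
            const double *s = src + base + (arma::uword)sw * H;
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

static void add_bias_relu(arma::mat &x, const arma::vec &b, bool relu) {
  for (arma::uword c = 0; c < x.n_cols; ++c) {
    double *p = x.colptr(c);
    const double bc = b[c];
    for (arma::uword r = 0; r < x.n_rows; ++r) {
      double v = p[r] + bc;
      if (relu && v < 0) v = 0;
      p[r] = v;
    }
  }
}

// layers: list of stages, each a list with folded conv weight matrices
// (k*k*Cin x Cout) and bias vectors: sW/sb (stage conv), b1W/b1b (branch
// conv1), b2W/b2b (branch conv2), plus kernel size k.
// [[Rcpp::export]]
NumericMatrix backbone_forward_cpp(NumericVector x, int H, int W, int N,
                                   int C, List layers, NumericMatrix att_W,
                                   NumericMatrix head_W, NumericVector head_b) {
  const arma::uword HWN = (arma::uword)H * W * N;
  arma::mat cur(x.begin(), HWN, C);  // copy

  for (R_xlen_t li = 0; li < layers.size(); ++li) {
    List st = layers[li];
    const int k = as<int>(st["k"]);
    arma::mat sW = as<arma::mat>(st["sW"]);
    arma::vec sb = as<arma::vec>(st["sb"]);
    arma::mat b1W = as<arma::mat>(st["b1W"]);
    arma::vec b1b = as<arma::vec>(st["b1b"]);
    arma::mat b2W = as<arma::mat>(st["b2W"]);
    arma::vec b2b = as<arma::vec>(st["b2b"]);

    arma::mat h = im2col_mat(cur, H, W, N, k) * sW;
    add_bias_relu(h, sb, true);
    arma::mat f = im2col_mat(h, H, W, N, k) * b1W;
    add_bias_relu(f, b1b, true);
    arma::mat f2 = im2col_mat(f, H, W, N, k) * b2W;
    add_bias_relu(f2, b2b, false);
    cur = h + f2;
  }

  // sigmoid channel attention + global average pooling
  const int Cf = cur.n_cols;
  const arma::uword HWu = (arma::uword)H * W;
  arma::mat aW(att_W.begin(), att_W.nrow(), att_W.ncol(), false);
  arma::mat feat(Cf, N);
  for (int c = 0; c < Cf; ++c) {
    const double *colp = cur.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double *blkp = colp + (arma::uword)n * HWu;
      double s = 0.0, m = 0.0;
      for (arma::uword r = 0; r < HWu; ++r) {
        s += aW(c, r) * blkp[r];
        m += blkp[r];
      }
      const double z = 1.0 / (1.0 + std::exp(-s));
      feat(c, n) = z * m / (double)HWu;
    }
  }

  arma::mat hW(head_W.begin(), head_W.nrow(), head_W.ncol(), false);
  arma::vec hb(head_b.begin(), head_b.size(), false);
  arma::mat logits = hW * feat;
  logits.each_col() += hb;

  // column softmax
  NumericMatrix out(N, logits.n_rows);
  for (int n = 0; n < N; ++n) {
    arma::vec col = logits.col(n);
    col -= col.max();
    arma::vec e = arma::exp(col);
    e /= arma::accu(e);
    for (arma::uword kk = 0; kk < e.n_elem; ++kk) out(n, kk) = e[kk];
  }
  return out;
}
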