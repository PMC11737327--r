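#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout convention used throughout the package:
// an H x W x C image is a column-major vector with element (h, w, c) at
// h + H*w + H*W*c (0-based); a batch of N images is an (H*W*C) x N matrix.

// im2col for 'same' convolution with an odd square kernel.
// Output: (C*k*k) x (H*W*N); column p + H*W*j holds the patch centred on
// output pixel p = h + H*w of image j, rows ordered u + k*v + k*k*c.
// [[Rcpp::export]]
NumericMatrix im2col_same(const NumericMatrix& X, int H, int W, int C, int k) {
  const int N = X.ncol();
  const int pad = (k - 1) / 2;
  const int P = H * W;
  NumericMatrix out(C * k * k, P * N);
  for (int j = 0; j < N; ++j) {
    const double* xj = &X(0, j);
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = &out(0, (h + H * w) + P * j);
        for (int c = 0; c < C; ++c) {
          const double* xc = xj + H * W * c;
          for (int v = 0; v < k; ++v) {
            const int ww = w + v - pad;
            const bool win = (ww >= 0 && ww < W);
            for (int u = 0; u < k; ++u) {
              const int hh = h + u - pad;
              col[u + k * v + k * k * c] =
                (win && hh >= 0 && hh < H) ? xc[hh + H * ww] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_same: scatter-add patch gradients back onto images.
// [[Rcpp::export]]
NumericMatrix col2im_same(const NumericMatrix& G, int H, int W, int C, int k,
                          int N) {
  const int pad = (k - 1) / 2;
  const int P = H * W;
  NumericMatrix out(H * W * C, N);
  for (int j = 0; j < N; ++j) {
    double* xj = &out(0, j);
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* col = &G(0, (h + H * w) + P * j);
        for (int c = 0; c < C; ++c) {
          double* xc = xj + H * W * c;
          for (int v = 0; v < k; ++v) {
            const int ww = w + v - pad;
            if (ww < 0 || ww >= W) continue;
            for (int u = 0; u < k; ++u) {
              const int hh = h + u - pad;
              if (hh < 0 || hh >= H) continue;
              xc[hh + H * ww] += col[u + k * v + k * k * c];
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling; a trailing odd row/column is dropped.
// Returns the pooled batch and the 1-based argmax linear index (into the
// input column) of every pooled element, for the backward pass.
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& X, int H, int W, int C) {
  const int N = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out(Ho * Wo * C, N);
  IntegerMatrix arg(Ho * Wo * C, N);
  for (int j = 0; j < N; ++j) {
    const double* xj = &X(0, j);
    for (int c = 0; c < C; ++c) {
      const int off = H * W * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = off + (2 * ho) + H * (2 * wo);
          double bv = xj[best];
          for (int dv = 0; dv < 2; ++dv) {
            for (int du = 0; du < 2; ++du) {
              const int idx = off + (2 * ho + du) + H * (2 * wo + dv);
              if (xj[idx] > bv) { bv = xj[idx]; best = idx; }
            }
          }
          const int o = ho + Ho * wo + Ho * Wo * c;
          out(o, j) = bv;
          arg(o, j) = best + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Backward of maxpool2: route gradients to the recorded argmax cells.
// [[Rcpp::export]]
NumericMatrix maxpool2_backward(const NumericMatrix& G,
                                const IntegerMatrix& arg,
                                int H, int W, int C) {
  const int N = G.ncol();
  NumericMatrix out(H * W * C, N);
  const int M = G.nrow();
  for (int j = 0; j < N; ++j) {
    for (int o = 0; o < M; ++o) {
      out(arg(o, j) - 1, j) += G(o, j);
    }
  }
  return out;
}
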