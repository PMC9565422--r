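#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored channels-first: a 4-D array with dim (C, H, W, N),
// column-major, so channel index varies fastest. im2col lowers convolution to
// a single matrix product; col2im is its adjoint (scatter-add), which makes
// both operations linear maps and keeps higher-order gradients exact.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int rows = C * k * k;
  R_xlen_t cols = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(rows, cols);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
        double *dst = po + col * rows;
        int h0 = ho * stride - pad;
        int w0 = wo * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          int w = w0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = h0 + ki;
            R_xlen_t r = (R_xlen_t)C * (ki + k * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double *src = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) dst[r + c] = src[c];
            }
            // zero padding: out was zero-initialised
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int rows = C * k * k;
  NumericVector x((R_xlen_t)C * H * W * N);
  const double *pc = cols.begin();
  double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * n;
        const double *src = pc + col * rows;
        int h0 = ho * stride - pad;
        int w0 = wo * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          int w = w0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = h0 + ki;
            R_xlen_t r = (R_xlen_t)C * (ki + k * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              double *dst = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) dst[c] += src[r + c];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// 2x2 max pooling with stride 2 on a (C, H, W, N) array. Returns the pooled
// values and the 1-based flat index of each winner so the backward pass is a
// plain scatter.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int C, int H, int W, int N) {
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t nout = (R_xlen_t)C * Ho * Wo * N;
  NumericVector out(nout);
  NumericVector idx(nout);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int h = 2 * ho + di, w = 2 * wo + dj;
              R_xlen_t i = c + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              if (px[i] > best) { best = px[i]; besti = i; }
            }
          R_xlen_t o = c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
          out[o] = best;
          idx[o] = (double)(besti + 1);
        }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["value"] = out, _["idx"] = idx);
}
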