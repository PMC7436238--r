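#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: feature maps are column-major arrays of dim (C, H, W, N),
// i.e. channel fastest. im2col unrolls k x k patches so a convolution becomes
// one matrix product  W[Cout x C*k*k] %*% cols[C*k*k x Ho*Wo*N].
// Row index of cols:  c + C*(ki + k*kj); column index: ho + Ho*(wo + Wo*n).

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_chw(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int rows = C * k * k;
  NumericMatrix cols(rows, Ho * Wo * N);
  const double* xp = x.begin();
  double* cp = cols.begin();

  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        double* col = cp + (R_xlen_t)rows * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            double* dst = col + C * (ki + k * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src = xn + (R_xlen_t)C * (h + (R_xlen_t)H * w);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of im2col: dcols (C*k*k x Ho*Wo*N) -> dx (C,H,W,N).
// [[Rcpp::export]]
NumericVector col2im_chw(NumericMatrix dcols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int rows = C * k * k;
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double* cp = dcols.begin();
  double* xp = dx.begin();

  for (int n = 0; n < N; ++n) {
    double* xn = xp + (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * stride - pad;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad;
        const double* col = cp + (R_xlen_t)rows * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            if (h < 0 || h >= H) continue;
            const double* src = col + C * (ki + k * kj);
            double* dst = xn + (R_xlen_t)C * (h + (R_xlen_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}
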