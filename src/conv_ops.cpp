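#include <Rcpp.h>
using namespace Rcpp;

// Image tensors are R arrays in (H, W, C, N) layout, column-major.
// im2col unrolls k x k patches so convolution becomes one BLAS gemm in R.

// [[Rcpp::export]]
NumericMatrix im2col_batch(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * C, oh * ow * N);
  const double *xp = x.begin();
  double *cp = cols.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (size_t)n * H * W * C;
    for (int oj = 0; oj < ow; ++oj) {
      const int j0 = oj * stride - pad;
      for (int oi = 0; oi < oh; ++oi) {
        const int i0 = oi * stride - pad;
        double *col = cp + (size_t)nrow * (oi + (size_t)oh * oj + (size_t)oh * ow * n);
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j0 + kj;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i0 + ki;
              col[ki + k * kj + k * k * c] =
                (i >= 0 && i < H && j >= 0 && j < W) ? xc[i + (size_t)H * j] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_batch(NumericMatrix cols, int H, int W, int C, int N,
                           int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector x( (size_t)H * W * C * N );
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (size_t)n * H * W * C;
    for (int oj = 0; oj < ow; ++oj) {
      const int j0 = oj * stride - pad;
      for (int oi = 0; oi < oh; ++oi) {
        const int i0 = oi * stride - pad;
        const double *col = cp + (size_t)nrow * (oi + (size_t)oh * oj + (size_t)oh * ow * n);
        for (int c = 0; c < C; ++c) {
          double *xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              xc[i + (size_t)H * j] += col[ki + k * kj + k * k * c];
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = (H - k) / stride + 1;
  const int ow = (W - k) / stride + 1;
  NumericVector out((size_t)oh * ow * C * N);
  IntegerVector idx((size_t)oh * ow * C * N);  // flat 0-based index into x
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  idx.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double *xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)n * H * W * C + (size_t)c * H * W;
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          // column-major output order is (oi fastest) but we loop oj outer for
          // cache friendliness on input; compute explicit output offset
          const size_t oo = (size_t)oi + (size_t)oh * oj + (size_t)oh * ow * c +
                            (size_t)oh * ow * C * n;
          double best = R_NegInf; size_t bi = 0;
          for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
              const size_t ii = base + (oi * stride + ki) +
                                (size_t)H * (oj * stride + kj);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          }
          out[oo] = best; idx[oo] = (int)bi;
          ++o;
        }
      }
    }
  }
  (void)o;
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector idx,
                          int H, int W, int C, int N) {
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dp = dout.begin();
  double *xp = dx.begin();
  const R_xlen_t M = dout.size();
  for (R_xlen_t t = 0; t < M; ++t) xp[idx[t]] += dp[t];
  return dx;
}
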