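// Compiled kernels for the 1-D CNN: im2col/col2im reshuffles and the
// batch-norm column broadcasts, the memory-bound inner loops of
// training. All matrices are column-major with the batch index fastest,
// matching R's array layout.

#include <Rcpp.h>
using namespace Rcpp;

// (N, L, C) array -> (N*Lo, k*C) sliding-tap matrix; each (tap, channel)
// column is one contiguous memcpy because slices over the time axis are
// contiguous blocks.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int k) {
  IntegerVector d = X.attr("dim");
  const int N = d[0], L = d[1], C = d[2];
  const int Lo = L - k + 1;
  NumericMatrix out((R_xlen_t)N * Lo, k * C);
  const double* x = X.begin();
  double* o = out.begin();
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      double* ocol = o + (R_xlen_t)(j * C + c) * N * Lo;
      const double* xbase = x + (R_xlen_t)c * N * L + (R_xlen_t)j * N;
      std::copy(xbase, xbase + (R_xlen_t)N * Lo, ocol);
    }
  return out;
}

// Adjoint of im2col: accumulate tap-gradients back onto the input array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dXc, int N, int L, int C, int k) {
  const int Lo = L - k + 1;
  NumericVector dX((R_xlen_t)N * L * C);
  dX.attr("dim") = IntegerVector::create(N, L, C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      const double* src = dXc.begin() + (R_xlen_t)(j * C + c) * N * Lo;
      double* dst = dX.begin() + (R_xlen_t)c * N * L + (R_xlen_t)j * N;
      const R_xlen_t n = (R_xlen_t)N * Lo;
      for (R_xlen_t i = 0; i < n; ++i) dst[i] += src[i];
    }
  return dX;
}

// out[, j] = M[, j] * scale[j] + shift[j]
// [[Rcpp::export]]
NumericMatrix col_scale_shift(NumericMatrix M, NumericVector scale,
                              NumericVector shift) {
  const int n = M.nrow(), p = M.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double s = scale[j], sh = shift[j];
    const double* src = M.begin() + (R_xlen_t)j * n;
    double* dst = out.begin() + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) dst[i] = src[i] * s + sh;
  }
  return out;
}

// Batch-norm backward for one layer. Inputs: upstream gradient dZn
// (post-affine, post-ReLU-mask), the cached normalized activations xhat,
// and the per-column gamma and 1/sd. Returns dZ (gradient wrt the
// pre-norm responses, using batch statistics) plus dgamma, dbeta.
// [[Rcpp::export]]
List bn_backward_cpp(NumericMatrix dZn, NumericMatrix xhat,
                     NumericVector gamma, NumericVector istd) {
  const int n = dZn.nrow(), p = dZn.ncol();
  NumericMatrix dZ(n, p);
  NumericVector dgamma(p), dbeta(p);
  for (int j = 0; j < p; ++j) {
    const double* a = dZn.begin() + (R_xlen_t)j * n;
    const double* xh = xhat.begin() + (R_xlen_t)j * n;
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = a[i] * gamma[j];
      s1 += dx; s2 += dx * xh[i];
      sg += a[i] * xh[i]; sb += a[i];
    }
    dgamma[j] = sg; dbeta[j] = sb;
    const double m1 = s1 / n, m2 = s2 / n, is = istd[j], g = gamma[j];
    double* dst = dZ.begin() + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i)
      dst[i] = (a[i] * g - m1 - xh[i] * m2) * is;
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
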