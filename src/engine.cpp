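// Hot inner loops of the network engine: the im2col gather and its
// scatter-add adjoint.  Index matrices are 0-padded (a 0 means the
// padding region outside the signal).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_gather")]]
NumericMatrix cpp_gather(const NumericMatrix& X, const IntegerMatrix& g) {
  const int n = g.nrow(), K = g.ncol(), C = X.ncol();
  NumericMatrix cols(n, K * C);
  for (int k = 0; k < K; ++k) {
    const int col0 = k * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = &X(0, c);
      double* out = &cols(0, col0 + c);
      const int* gk = &g(0, k);
      for (int r = 0; r < n; ++r) {
        const int src = gk[r];
        out[r] = (src > 0) ? xc[src - 1] : 0.0;
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".cpp_scatter_add")]]
NumericMatrix cpp_scatter_add(const NumericMatrix& U, const IntegerMatrix& g,
                              int n_rows, int C) {
  const int n = g.nrow(), K = g.ncol();
  NumericMatrix Y(n_rows, C);
  for (int k = 0; k < K; ++k) {
    const int col0 = k * C;
    for (int c = 0; c < C; ++c) {
      const double* uc = &U(0, col0 + c);
      double* yc = &Y(0, c);
      const int* gk = &g(0, k);
      for (int r = 0; r < n; ++r) {
        const int dst = gk[r];
        if (dst > 0) yc[dst - 1] += uc[r];
      }
    }
  }
  return Y;
}
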