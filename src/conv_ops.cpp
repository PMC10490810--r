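#include <Rcpp.h>
using namespace Rcpp;

// 1-D im2col in the flat activation layout ((batch * length) x channels,
// rows ordered batch-fastest): column (c-1)*K + k of the result is rows
// s + B*(k-1) of column c of the input, s = 1..B*Lout.

// [[Rcpp::export(name = ".im2col_1d")]]
NumericMatrix im2col_1d(const NumericMatrix& a, int B, int L, int K) {
  const int Cin = a.ncol();
  const int Lout = L - K + 1;
  const int n = B * Lout;
  NumericMatrix out(n, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* src = &a(0, c);
    for (int k = 0; k < K; ++k) {
      double* dst = &out(0, c * K + k);
      const double* s = src + B * k;
      std::copy(s, s + n, dst);
    }
  }
  return out;
}

// adjoint of im2col: scatter-add the column gradient back onto the input
// [[Rcpp::export(name = ".col2im_1d")]]
NumericMatrix col2im_1d(const NumericMatrix& dxcol, int B, int L, int K,
                        int Cin) {
  const int Lout = L - K + 1;
  const int n = B * Lout;
  NumericMatrix dA(B * L, Cin);
  for (int c = 0; c < Cin; ++c) {
    double* dst = &dA(0, c);
    for (int k = 0; k < K; ++k) {
      const double* src = &dxcol(0, c * K + k);
      double* d = dst + B * k;
      for (int i = 0; i < n; ++i) d[i] += src[i];
    }
  }
  return dA;
}
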