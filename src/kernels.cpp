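// Hot inner kernels of the autodiff engine: im2col gather / col2im scatter
// for 3x3 and 7x7 convolutions, and the block-diagonal application of
// per-window attention scores to value rows.
#include <Rcpp.h>
using namespace Rcpp;

// idx is (H*W) x K, 1-based, with H*W + 1 marking a zero-padded position.
// Output column layout: c * K + q (channel-major, kernel position fastest).
// [[Rcpp::export]]
NumericMatrix im2col_gather(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int HW = idx.nrow(), K = idx.ncol(), Cin = x.ncol();
  const int nx = x.nrow();
  NumericMatrix out(HW, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = &x(0, c);
    for (int q = 0; q < K; ++q) {
      double* oc = &out(0, c * K + q);
      const int* ic = &idx(0, q);
      for (int p = 0; p < HW; ++p) {
        const int src = ic[p];
        oc[p] = (src <= nx) ? xc[src - 1] : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_scatter(const NumericMatrix& dXcol, const IntegerMatrix& idx,
                             const int Cin) {
  const int HW = idx.nrow(), K = idx.ncol();
  NumericMatrix dx(HW, Cin);
  for (int c = 0; c < Cin; ++c) {
    double* dc = &dx(0, c);
    for (int q = 0; q < K; ++q) {
      const double* gc = &dXcol(0, c * K + q);
      const int* ic = &idx(0, q);
      for (int p = 0; p < HW; ++p) {
        const int src = ic[p];
        if (src <= HW) dc[src - 1] += gc[p];
      }
    }
  }
  return dx;
}

// out[(w,i), ] = sum_j A[(w,i), j] * V[(w,j), ], rows grouped in windows of Nw
// [[Rcpp::export]]
NumericMatrix win_apply_fw(const NumericMatrix& A, const NumericMatrix& V,
                           const int Nw) {
  const int n = A.nrow(), dv = V.ncol();
  NumericMatrix out(n, dv);
  for (int c = 0; c < dv; ++c) {
    const double* vc = &V(0, c);
    double* oc = &out(0, c);
    for (int r = 0; r < n; ++r) {
      const int base = (r / Nw) * Nw;
      double acc = 0.0;
      for (int j = 0; j < Nw; ++j) acc += A(r, j) * vc[base + j];
      oc[r] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List win_apply_bw(const NumericMatrix& g, const NumericMatrix& A,
                  const NumericMatrix& V, const int Nw) {
  const int n = A.nrow(), dv = V.ncol();
  NumericMatrix dA(n, Nw), dV(n, dv);
  for (int c = 0; c < dv; ++c) {
    const double* vc = &V(0, c);
    const double* gc = &g(0, c);
    double* dvc = &dV(0, c);
    for (int r = 0; r < n; ++r) {
      const int base = (r / Nw) * Nw;
      const double gr = gc[r];
      for (int j = 0; j < Nw; ++j) {
        dA(r, j) += gr * vc[base + j];
        dvc[base + j] += gr * A(r, j);
      }
    }
  }
  return List::create(Named("dA") = dA, Named("dV") = dV);
}
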