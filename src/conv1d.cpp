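// Hot path of the 1D convolution layers: im2col forward and col2im backward.
// Layouts match the R side: x is (batch, time, channel) in column-major
// order; col is (batch*lout, kernel*channel); W is (kernel*channel, f).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".conv1d_im2col")]]
arma::mat conv1d_im2col(const arma::cube& x, int kernel, int stride, int pad) {
  const int b = x.n_rows, t = x.n_cols, c = x.n_slices;
  const int tp = t + 2 * pad;
  const int lout = (tp - kernel) / stride + 1;
  arma::mat col(b * lout, kernel * c);
  for (int ch = 0; ch < c; ++ch) {
    for (int k = 0; k < kernel; ++k) {
      const int jcol = k + ch * kernel;
      for (int l = 0; l < lout; ++l) {
        const int tin = l * stride + k - pad; // position in the unpadded input
        double* dst = col.colptr(jcol) + (size_t)l * b;
        if (tin < 0 || tin >= t) {
          std::fill(dst, dst + b, 0.0);
        } else {
          const double* src = x.memptr() + ((size_t)ch * t + tin) * b;
          std::copy(src, src + b, dst);
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv1d_col2im")]]
arma::cube conv1d_col2im(const arma::mat& dcol, int b, int t, int c,
                         int kernel, int stride, int pad) {
  const int tp = t + 2 * pad;
  const int lout = (tp - kernel) / stride + 1;
  arma::cube dx(b, t, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int k = 0; k < kernel; ++k) {
      const int jcol = k + ch * kernel;
      for (int l = 0; l < lout; ++l) {
        const int tin = l * stride + k - pad;
        if (tin < 0 || tin >= t) continue;
        const double* src = dcol.colptr(jcol) + (size_t)l * b;
        double* dst = dx.memptr() + ((size_t)ch * t + tin) * b;
        for (int i = 0; i < b; ++i) dst[i] += src[i];
      }
    }
  }
  return dx;
}
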