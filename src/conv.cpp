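// Hot path of the encoder-decoder: 3x3 same-padding convolution forward and
// backward via im2col + BLAS gemm. Column layout matches the R caller: for
// each of the 9 taps (dx, dy in column-major order), all input channels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
List conv3x3_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b) {
  const arma::uword n1 = x.n_rows, n2 = x.n_cols, cin = x.n_slices;
  const arma::uword npix = n1 * n2, cout = W.n_cols;
  arma::mat col(npix, 9 * cin);
  for (arma::uword c = 0; c < cin; ++c) {
    const arma::mat& xs = x.slice(c);
    arma::uword o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        double* dst = col.colptr(o * cin + c);
        for (arma::uword j = 0; j < n2; ++j) {
          const long js = (long)j + dx;
          if (js < 0 || js >= (long)n2) {
            std::memset(dst + j * n1, 0, n1 * sizeof(double));
            continue;
          }
          const double* src = xs.colptr(js);
          double* out = dst + j * n1;
          const long lo = (dy < 0) ? -dy : 0;          // first valid output row
          const long hi = (dy > 0) ? n1 - dy : n1;     // one past last valid
          if (lo > 0) std::memset(out, 0, lo * sizeof(double));
          if (hi < (long)n1) std::memset(out + hi, 0, (n1 - hi) * sizeof(double));
          std::memcpy(out + lo, src + lo + dy, (hi - lo) * sizeof(double));
        }
      }
    }
  }
  arma::mat y = col * W;
  y.each_row() += b.t();
  arma::cube yc(y.memptr(), n1, n2, cout);
  return List::create(_["y"] = yc, _["col"] = col);
}

// [[Rcpp::export(rng = false)]]
List conv3x3_bwd(const arma::cube& gy, const arma::mat& col, const arma::mat& W,
                 int n1_, int n2_, int cin_) {
  const arma::uword n1 = n1_, n2 = n2_, cin = cin_;
  const arma::uword npix = n1 * n2;
  arma::mat gym(const_cast<double*>(gy.memptr()), npix, gy.n_slices, false, true);
  arma::mat gW = col.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcol = gym * W.t();
  arma::cube gx(n1, n2, cin, arma::fill::zeros);
  for (arma::uword c = 0; c < cin; ++c) {
    arma::mat& gxs = gx.slice(c);
    arma::uword o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        const double* src = gcol.colptr(o * cin + c);
        for (arma::uword j = 0; j < n2; ++j) {
          const long js = (long)j + dx;
          if (js < 0 || js >= (long)n2) continue;
          double* dst = gxs.colptr(js);
          const long lo = (dy < 0) ? -dy : 0;
          const long hi = (dy > 0) ? n1 - dy : n1;
          const double* s = src + j * n1 + lo;
          double* d = dst + lo + dy;
          for (long i = lo; i < hi; ++i) *d++ += *s++;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
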