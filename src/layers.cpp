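// Elementwise ReLU and 2x2x2 max pooling on (N, C, B)-layout activations.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
List relu_fwd_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  LogicalVector mask(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = x[i];
    if (v > 0) {
      y[i] = v;
      mask[i] = true;
    }
  }
  return List::create(Named("y") = y, Named("mask") = mask);
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dy, LogicalVector mask) {
  R_xlen_t n = dy.size();
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) dx[i] = dy[i];
  return dx;
}

// [[Rcpp::export(name = ".pool_fwd_cpp")]]
List pool_fwd_cpp(NumericVector x, IntegerVector shape, int cb) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t n_in = (size_t)nx * ny * nz, n_out = (size_t)ox * oy * oz;
  NumericVector y((R_xlen_t)(n_out * cb));
  IntegerVector arg((R_xlen_t)(n_out * cb));
  for (int c = 0; c < cb; ++c) {
    const double* xc = x.begin() + (size_t)c * n_in;
    double* yc = y.begin() + (size_t)c * n_out;
    int* ac = arg.begin() + (size_t)c * n_out;
    size_t o = 0;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx, ++o) {
          double best = -HUGE_VAL;
          int bestidx = 0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                const size_t idx = (size_t)(2 * xx + kx) +
                  (size_t)(2 * yy + ky) * nx + (size_t)(2 * z + kz) * nx * ny;
                if (xc[idx] > best) {
                  best = xc[idx];
                  bestidx = (int)idx;
                }
              }
          yc[o] = best;
          ac[o] = bestidx;
        }
  }
  return List::create(Named("y") = y, Named("arg") = arg);
}

// [[Rcpp::export(name = ".pool_bwd_cpp")]]
NumericVector pool_bwd_cpp(NumericVector dy, IntegerVector arg,
                           IntegerVector shape, int cb) {
  const size_t n_in = (size_t)shape[0] * shape[1] * shape[2];
  const size_t n_out = dy.size() / cb;
  NumericVector dx((R_xlen_t)(n_in * cb));
  for (int c = 0; c < cb; ++c) {
    const double* dyc = dy.begin() + (size_t)c * n_out;
    const int* ac = arg.begin() + (size_t)c * n_out;
    double* dxc = dx.begin() + (size_t)c * n_in;
    for (size_t o = 0; o < n_out; ++o) dxc[ac[o]] += dyc[o];
  }
  return dx;
}
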