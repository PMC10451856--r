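// 3D convolution (3x3x3 kernel, stride 1, zero padding 1) forward and
// backward. Activations use the package layout (N, C, B): flattened
// spatial positions fastest, then channels, then batch. im2col buffers are
// built per sample with pointer loops; the contractions go through BLAS
// via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// xpad: padded sample, (nx+2)(ny+2)(nz+2) * cin; col: (27*cin) x N with
// row index r = k + c*27 (kernel tap fastest), matching the R-side kernel
// matrix layout (cout x 27*cin).
static void im2col3(const double* xpad, int nx, int ny, int nz, int cin,
                    double* col) {
  const int px = nx + 2, py = ny + 2;
  const size_t npad = (size_t)px * py * (nz + 2);
  size_t n = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++n) {
        double* out = col + n * 27 * cin;
        for (int c = 0; c < cin; ++c) {
          const double* base = xpad + (size_t)c * npad;
          double* oc = out + c * 27;
          int k = 0;
          for (int kz = 0; kz < 3; ++kz)
            for (int ky = 0; ky < 3; ++ky)
              for (int kx = 0; kx < 3; ++kx, ++k)
                oc[k] = base[(x + kx) + (size_t)(y + ky) * px +
                             (size_t)(z + kz) * px * py];
        }
      }
}

static void pad_sample(const double* x, int nx, int ny, int nz, int cin,
                       size_t n, double* xpad) {
  const int px = nx + 2, py = ny + 2;
  const size_t npad = (size_t)px * py * (nz + 2);
  std::fill(xpad, xpad + npad * cin, 0.0);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * n;
    double* pc = xpad + (size_t)c * npad;
    size_t i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x0 = 0; x0 < nx; ++x0, ++i)
          pc[(x0 + 1) + (size_t)(y + 1) * px + (size_t)(z + 1) * px * py] = xc[i];
  }
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
List conv3d_fwd_cpp(NumericVector x, IntegerVector shape, int cin, int nb,
                    NumericMatrix w, NumericVector bias, bool relu) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const size_t n = (size_t)nx * ny * nz;
  const int cout = w.nrow();
  const size_t npad = (size_t)(nx + 2) * (ny + 2) * (nz + 2);
  NumericVector y((R_xlen_t)(n * cout * nb));
  LogicalVector mask(relu ? (R_xlen_t)(n * cout * nb) : 0);
  std::vector<double> xpad(npad * cin), col(27 * (size_t)cin * n);
  arma::mat W(w.begin(), cout, 27 * cin, false, true);
  for (int s = 0; s < nb; ++s) {
    pad_sample(x.begin() + (size_t)s * n * cin, nx, ny, nz, cin, n, xpad.data());
    im2col3(xpad.data(), nx, ny, nz, cin, col.data());
    arma::mat C(col.data(), 27 * cin, n, false, true);
    arma::mat O = W * C; // cout x n
    double* ys = y.begin() + (size_t)s * n * cout;
    int* ms = relu ? (mask.begin() + (size_t)s * n * cout) : nullptr;
    for (int co = 0; co < cout; ++co) {
      const double b0 = bias[co];
      double* yc = ys + (size_t)co * n;
      if (relu) {
        int* mc = ms + (size_t)co * n;
        for (size_t i = 0; i < n; ++i) {
          const double v = O(co, i) + b0;
          yc[i] = v > 0 ? v : 0.0;
          mc[i] = v > 0;
        }
      } else {
        for (size_t i = 0; i < n; ++i) yc[i] = O(co, i) + b0;
      }
    }
  }
  return List::create(Named("y") = y, Named("mask") = mask);
}

// dy is the gradient at the (post-ReLU) layer output; if mask is
// non-empty it is applied to dy on the fly.
// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector x, NumericVector dy, IntegerVector shape,
                    int cin, int nb, NumericMatrix w, bool need_dx,
                    LogicalVector mask) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  const size_t n = (size_t)nx * ny * nz;
  const int cout = w.nrow();
  const int px = nx + 2, py = ny + 2;
  const size_t npad = (size_t)px * py * (nz + 2);
  arma::mat W(w.begin(), cout, 27 * cin, false, true);
  arma::mat dWT(27 * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx(need_dx ? (R_xlen_t)(n * cin * nb) : 0);
  const bool use_mask = mask.size() > 0;
  std::vector<double> xpad(npad * cin), col(27 * (size_t)cin * n),
      dpad(npad * cin), dbuf(use_mask ? n * cout : 0);
  for (int s = 0; s < nb; ++s) {
    pad_sample(x.begin() + (size_t)s * n * cin, nx, ny, nz, cin, n, xpad.data());
    im2col3(xpad.data(), nx, ny, nz, cin, col.data());
    arma::mat C(col.data(), 27 * cin, n, false, true);
    double* dsrc = const_cast<double*>(dy.begin()) + (size_t)s * n * cout;
    if (use_mask) {
      const int* ms = mask.begin() + (size_t)s * n * cout;
      for (size_t i = 0; i < n * (size_t)cout; ++i)
        dbuf[i] = ms[i] ? dsrc[i] : 0.0;
      dsrc = dbuf.data();
    }
    arma::mat D(dsrc, n, cout, false, true);
    dWT += C * D;
    db += arma::sum(D, 0).t();
    if (need_dx) {
      arma::mat dCol = W.t() * D.t(); // (27*cin) x n
      std::fill(dpad.begin(), dpad.end(), 0.0);
      size_t pos = 0;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x0 = 0; x0 < nx; ++x0, ++pos) {
            const double* src = dCol.colptr(pos);
            for (int c = 0; c < cin; ++c) {
              double* pc = dpad.data() + (size_t)c * npad;
              const double* sc = src + c * 27;
              int k = 0;
              for (int kz = 0; kz < 3; ++kz)
                for (int ky = 0; ky < 3; ++ky)
                  for (int kx = 0; kx < 3; ++kx, ++k)
                    pc[(x0 + kx) + (size_t)(y + ky) * px +
                       (size_t)(z + kz) * px * py] += sc[k];
            }
          }
      double* dxs = dx.begin() + (size_t)s * n * cin;
      for (int c = 0; c < cin; ++c) {
        const double* pc = dpad.data() + (size_t)c * npad;
        double* dc = dxs + (size_t)c * n;
        size_t i = 0;
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y)
            for (int x0 = 0; x0 < nx; ++x0, ++i)
              dc[i] = pc[(x0 + 1) + (size_t)(y + 1) * px +
                         (size_t)(z + 1) * px * py];
      }
    }
  }
  NumericMatrix dw(cout, 27 * cin);
  for (int co = 0; co < cout; ++co)
    for (int r = 0; r < 27 * cin; ++r) dw(co, r) = dWT(r, co);
  return List::create(Named("dw") = dw,
                      Named("db") = NumericVector(db.begin(), db.end()),
                      Named("dx") = dx);
}
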