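// Batched scaled-dot-product attention core. Queries come from xq, keys
// and values from xkv (xq == xkv for self-attention). Layout (N, C, B).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void row_softmax_inplace(arma::mat& s) {
  for (arma::uword i = 0; i < s.n_rows; ++i) {
    arma::rowvec r = s.row(i);
    r -= r.max();
    r = arma::exp(r);
    s.row(i) = r / arma::accu(r);
  }
}

// [[Rcpp::export(name = ".attn_fwd_cpp")]]
List attn_fwd_cpp(NumericVector xq, NumericVector xkv, int n, int c, int nb,
                  NumericMatrix wq, NumericMatrix wk, NumericMatrix wv) {
  const int dk = wq.ncol();
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat Wq(wq.begin(), c, dk, false, true);
  arma::mat Wk(wk.begin(), c, dk, false, true);
  arma::mat Wv(wv.begin(), c, c, false, true);
  NumericVector h((R_xlen_t)n * c * nb), a((R_xlen_t)n * n * nb),
      q((R_xlen_t)n * dk * nb), k((R_xlen_t)n * dk * nb),
      v((R_xlen_t)n * c * nb);
  for (int s = 0; s < nb; ++s) {
    arma::mat Xq(const_cast<double*>(xq.begin()) + (size_t)s * n * c, n, c,
                 false, true);
    arma::mat Xkv(const_cast<double*>(xkv.begin()) + (size_t)s * n * c, n, c,
                  false, true);
    arma::mat Q(q.begin() + (size_t)s * n * dk, n, dk, false, true);
    arma::mat K(k.begin() + (size_t)s * n * dk, n, dk, false, true);
    arma::mat V(v.begin() + (size_t)s * n * c, n, c, false, true);
    arma::mat A(a.begin() + (size_t)s * n * n, n, n, false, true);
    arma::mat H(h.begin() + (size_t)s * n * c, n, c, false, true);
    Q = Xq * Wq;
    K = Xkv * Wk;
    V = Xkv * Wv;
    A = Q * K.t() * scale;
    row_softmax_inplace(A);
    H = A * V;
  }
  return List::create(Named("h") = h, Named("a") = a, Named("q") = q,
                      Named("k") = k, Named("v") = v);
}

// [[Rcpp::export(name = ".attn_bwd_cpp")]]
List attn_bwd_cpp(NumericVector dh, NumericVector xq, NumericVector xkv,
                  int n, int c, int nb, NumericMatrix wq, NumericMatrix wk,
                  NumericMatrix wv, NumericVector a, NumericVector q,
                  NumericVector k, NumericVector v) {
  const int dk = wq.ncol();
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat Wq(wq.begin(), c, dk, false, true);
  arma::mat Wk(wk.begin(), c, dk, false, true);
  arma::mat Wv(wv.begin(), c, c, false, true);
  NumericVector dxq((R_xlen_t)n * c * nb), dxkv((R_xlen_t)n * c * nb);
  arma::mat dWq(c, dk, arma::fill::zeros), dWk(c, dk, arma::fill::zeros),
      dWv(c, c, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    arma::mat Xq(const_cast<double*>(xq.begin()) + (size_t)s * n * c, n, c,
                 false, true);
    arma::mat Xkv(const_cast<double*>(xkv.begin()) + (size_t)s * n * c, n, c,
                  false, true);
    arma::mat dH(const_cast<double*>(dh.begin()) + (size_t)s * n * c, n, c,
                 false, true);
    arma::mat A(const_cast<double*>(a.begin()) + (size_t)s * n * n, n, n,
                false, true);
    arma::mat Q(const_cast<double*>(q.begin()) + (size_t)s * n * dk, n, dk,
                false, true);
    arma::mat K(const_cast<double*>(k.begin()) + (size_t)s * n * dk, n, dk,
                false, true);
    arma::mat V(const_cast<double*>(v.begin()) + (size_t)s * n * c, n, c,
                false, true);
    arma::mat dA = dH * V.t();
    arma::mat dV = A.t() * dH;
    arma::mat AdA = A % dA;
    arma::vec rs = arma::sum(AdA, 1);
    arma::mat dS = AdA - (A.each_col() % rs);
    arma::mat dQ = dS * K * scale;
    arma::mat dK = dS.t() * Q * scale;
    arma::mat DXq(dxq.begin() + (size_t)s * n * c, n, c, false, true);
    arma::mat DXkv(dxkv.begin() + (size_t)s * n * c, n, c, false, true);
    DXq = dQ * Wq.t();
    DXkv = dK * Wk.t() + dV * Wv.t();
    dWq += Xq.t() * dQ;
    dWk += Xkv.t() * dK;
    dWv += Xkv.t() * dV;
  }
  return List::create(
      Named("dxq") = dxq, Named("dxkv") = dxkv,
      Named("dwq") = NumericMatrix(c, dk, dWq.begin()),
      Named("dwk") = NumericMatrix(c, dk, dWk.begin()),
      Named("dwv") = NumericMatrix(c, c, dWv.begin()));
}
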