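// Inner kernels for the selection probabilistic model trunk: forward and
// backward passes of the fully connected ReLU network, with unit dropout
// shared across the (full) batch. Matrix products use the BLAS through
// Armadillo; elementwise work is done in place over raw memory to avoid
// temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void reluInPlace(arma::mat& Z) {
  double* p = Z.memptr();
  const arma::uword n = Z.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (p[i] < 0.0) p[i] = 0.0;
}

static inline void dropScaleInPlace(arma::mat& Z, const arma::uvec& du,
                                    double scale) {
  for (arma::uword k = 0; k < du.n_elem; ++k) Z.col(du[k]).zeros();
  if (scale != 1.0) Z *= scale;
}

// mask delta by the support of the (post-dropout) activation
static inline void reluMaskInPlace(arma::mat& delta, const arma::mat& act) {
  double* d = delta.memptr();
  const double* a = act.memptr();
  const arma::uword n = delta.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (a[i] <= 0.0) d[i] = 0.0;
}

// forward pass; dropUnits: per hidden layer, 0-based indices of dropped
// units (empty list at inference); scale: inverted-dropout factor.
// Returns f and the post-activation hidden layers (for backprop).
// [[Rcpp::export(name = ".mlpForwardCpp")]]
List mlpForwardCpp(const List& W, const List& b, const arma::mat& X,
                   const List& dropUnits, double scale) {
  const int L = W.size();
  List H(L - 1);
  std::vector<arma::mat> hs(L - 1);
  const arma::mat* A = &X;
  for (int l = 0; l < L - 1; ++l) {
    arma::mat Wl = as<arma::mat>(W[l]);
    arma::rowvec bl = as<arma::rowvec>(b[l]);
    hs[l] = (*A) * Wl;
    hs[l].each_row() += bl;
    reluInPlace(hs[l]);
    if (dropUnits.size() > 0)
      dropScaleInPlace(hs[l], as<arma::uvec>(dropUnits[l]), scale);
    A = &hs[l];
  }
  arma::mat WL = as<arma::mat>(W[L - 1]);
  double bL = as<arma::vec>(b[L - 1])[0];
  arma::vec f = (*A) * WL.col(0) + bL;
  for (int l = 0; l < L - 1; ++l) H[l] = hs[l];
  return List::create(Named("f") = f, Named("H") = H);
}

// backward pass for dL/df = g; returns per-layer weight and bias grads.
// H must be the hidden activations returned by the forward pass under
// the same dropout draw.
// [[Rcpp::export(name = ".mlpBackwardCpp")]]
List mlpBackwardCpp(const List& W, const arma::mat& X, const List& H,
                    const arma::vec& g, const List& dropUnits,
                    double scale) {
  const int L = W.size();
  List gW(L), gb(L);
  std::vector<arma::mat> hs(L - 1);
  for (int l = 0; l < L - 1; ++l) hs[l] = as<arma::mat>(H[l]);
  const arma::mat& Alast = (L == 1) ? X : hs[L - 2];
  gW[L - 1] = arma::mat(Alast.t() * g);
  gb[L - 1] = arma::vec{arma::accu(g)};
  arma::mat WL = as<arma::mat>(W[L - 1]);
  arma::mat delta = g * WL.col(0).t();  // n x h
  for (int l = L - 2; l >= 0; --l) {
    reluMaskInPlace(delta, hs[l]);
    if (dropUnits.size() > 0)
      dropScaleInPlace(delta, as<arma::uvec>(dropUnits[l]), scale);
    const arma::mat& Aprev = (l == 0) ? X : hs[l - 1];
    gW[l] = arma::mat(Aprev.t() * delta);
    gb[l] = arma::vec(arma::sum(delta, 0).t());
    if (l > 0) delta = delta * as<arma::mat>(W[l]).t();
  }
  return List::create(Named("W") = gW, Named("b") = gb);
}
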