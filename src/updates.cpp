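// Fused single-pass optimizer updates. These run once per parameter tensor
// per mini-batch; doing the elementwise arithmetic in one pass (instead of
// half a dozen vectorized R temporaries) keeps desk-scale CNN training
// comfortably on one CPU.

#include <Rcpp.h>
using namespace Rcpp;

// w' = w - a * m' / (sqrt(v') + epsb), with m' and v' the updated first and
// second moment estimates; a and epsb carry the adam bias corrections.
// [[Rcpp::export(name = ".fused_adam")]]
List fused_adam(NumericVector w, NumericVector m, NumericVector v,
                NumericVector g, double a, double epsb) {
  R_xlen_t n = w.size();
  NumericVector w2(n), m2(n), v2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = 0.9 * m[i] + 0.1 * gi;
    double vi = 0.999 * v[i] + 0.001 * gi * gi;
    m2[i] = mi;
    v2[i] = vi;
    w2[i] = w[i] - a * mi / (std::sqrt(vi) + epsb);
  }
  return List::create(_["w"] = w2, _["m"] = m2, _["v"] = v2);
}

// classical momentum: m' = 0.9 m + g; w' = w - lr * m'
// [[Rcpp::export(name = ".fused_sgdm")]]
List fused_sgdm(NumericVector w, NumericVector m, NumericVector g,
                double lr) {
  R_xlen_t n = w.size();
  NumericVector w2(n), m2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = 0.9 * m[i] + g[i];
    m2[i] = mi;
    w2[i] = w[i] - lr * mi;
  }
  return List::create(_["w"] = w2, _["m"] = m2);
}

// v' = 0.9 v + 0.1 g^2; w' = w - lr * g / (sqrt(v') + 1e-8)
// [[Rcpp::export(name = ".fused_rmsprop")]]
List fused_rmsprop(NumericVector w, NumericVector v, NumericVector g,
                   double lr) {
  R_xlen_t n = w.size();
  NumericVector w2(n), v2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double vi = 0.9 * v[i] + 0.1 * gi * gi;
    v2[i] = vi;
    w2[i] = w[i] - lr * gi / (std::sqrt(vi) + 1e-8);
  }
  return List::create(_["w"] = w2, _["v"] = v2);
}
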