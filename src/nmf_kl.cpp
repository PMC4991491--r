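// Multiplicative-update NMF minimizing the generalized Kullback-Leibler
// divergence D(V || WH) = sum( V*log(V/WH) - V + WH ).  The classic
// Brunet-style updates keep W,H strictly non-negative; the objective is
// non-increasing at every step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_objective(const mat& V, const mat& WH) {
  // convention: terms with V==0 contribute WH (x*log(x) -> 0)
  double obj = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      double v = V(i, j), wh = WH(i, j);
      obj += (v > 0.0) ? v * std::log(v / wh) - v + wh : wh;
    }
  }
  return obj;
}

// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every,
                      bool trace_objective, int stable_stop) {
  // stable_stop > 0: additionally stop once the argmax-H sample
  // memberships are unchanged over that many consecutive checks
  // (connectivity-stability rule used for consensus clustering runs)
  const double eps = 1e-16;
  mat WH = W * H;
  double obj = kl_objective(V, WH);
  double prev = obj;
  int it = 0;
  std::vector<double> trace;
  if (trace_objective) trace.push_back(obj);
  uvec memb = index_max(H, 0).t();
  int stable = 0;

  for (it = 1; it <= max_iter; ++it) {
    // H update: H <- H * ( W' (V/WH) ) / ( W' 1 )
    mat Q = V / (WH + eps);
    vec wsum = sum(W, 0).t();              // k
    H %= (W.t() * Q);
    H.each_col() /= (wsum + eps);

    // W update with refreshed quotient
    WH = W * H;
    Q = V / (WH + eps);
    rowvec hsum = sum(H, 1).t();           // k
    W %= (Q * H.t());
    W.each_row() /= (hsum + eps);

    WH = W * H;
    if (trace_objective || it % check_every == 0 || it == max_iter) {
      obj = kl_objective(V, WH);
      if (trace_objective) trace.push_back(obj);
      if (it % check_every == 0 || it == max_iter) {
        double denom = std::abs(prev) + eps;
        if (std::abs(prev - obj) / denom < tol) break;
        prev = obj;
        if (stable_stop > 0) {
          uvec m2 = index_max(H, 0).t();
          if (accu(m2 != memb) == 0) {
            if (++stable >= stable_stop) break;
          } else {
            stable = 0;
            memb = m2;
          }
        }
      }
    }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("n_iterations") = it,
      Rcpp::Named("objective_trace") = trace);
}
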