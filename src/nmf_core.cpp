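// Multiplicative-update cores for signature discovery (W and H updated)
// and fixed-signature activity refitting (W held fixed). Updates are the
// KL-divergence ("Brunet") rules; both the KL objective and the Frobenius
// residual ||V - WH|| are traced. The KL objective is non-increasing by
// construction; the Frobenius residual is the quantity used for run
// selection and for the windowed asymptote stopping rule.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double kl_div(const arma::mat& V, const arma::mat& WH, double eps) {
  return arma::accu(V % arma::log((V + eps) / WH) - V + WH);
}

// [[Rcpp::export]]
List cpp_nmf_kl_run(const arma::mat& V, arma::mat W, arma::mat H,
                    int max_iter, double rel_tol, double eps) {
  const arma::mat Vt = V;
  std::vector<double> res_trace, div_trace;
  res_trace.reserve(max_iter);
  div_trace.reserve(max_iter);
  double prev_res = -1.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    arma::mat WH = W * H + eps;
    arma::vec csw = arma::sum(W, 0).t() + eps;
    H = H % (W.t() * (Vt / WH));
    H.each_col() /= csw;
    WH = W * H + eps;
    arma::rowvec rsh = arma::sum(H, 1).t() + eps;
    W = W % ((Vt / WH) * H.t());
    W.each_row() /= rsh;
    WH = W * H + eps;
    double res = arma::norm(Vt - WH, "fro");
    res_trace.push_back(res);
    div_trace.push_back(kl_div(Vt, WH, eps));
    if (prev_res >= 0.0 &&
        std::fabs(prev_res - res) < rel_tol * std::max(prev_res, eps)) {
      ++it;
      break;
    }
    prev_res = res;
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["residual_trace"] = res_trace,
                      _["divergence_trace"] = div_trace,
                      _["iterations"] = (int)res_trace.size());
}

// [[Rcpp::export]]
List cpp_refit_kl(const arma::mat& V, const arma::mat& W, arma::mat H,
                  double tol, int window, int max_iter, double eps) {
  std::vector<double> res_trace, div_trace;
  res_trace.reserve(256);
  div_trace.reserve(256);
  arma::vec csw = arma::sum(W, 0).t() + eps;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::mat WH = W * H + eps;
    H = H % (W.t() * (V / WH));
    H.each_col() /= csw;
    WH = W * H + eps;
    double res = arma::norm(V - WH, "fro");
    res_trace.push_back(res);
    div_trace.push_back(kl_div(V, WH, eps));
    int i = (int)res_trace.size();
    if (i > window) {
      double slope = (res_trace[i - 1 - window] - res_trace[i - 1]) / window;
      if (slope < tol) {
        converged = true;
        break;
      }
    }
  }
  return List::create(_["H"] = H,
                      _["residual_trace"] = res_trace,
                      _["divergence_trace"] = div_trace,
                      _["converged"] = converged,
                      _["iterations"] = (int)res_trace.size());
}
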