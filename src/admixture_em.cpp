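// EM core for the admixture model. The R wrapper handles initialization,
// seeding and result packaging; this loop only iterates the multiplicative
// updates and records the log-likelihood trace.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Galt: n x L alternate-allele counts (0 where missing)
// Gref: n x L reference-allele counts (0 where missing)
// L_i : per-sample number of called loci
// [[Rcpp::export(name = ".admixture_em_cpp")]]
Rcpp::List admixture_em_cpp(const arma::mat& Galt, const arma::mat& Gref,
                            arma::mat Q, arma::mat F, const arma::vec& L_i,
                            double tol, int max_iter) {
  const double f_lo = 1e-6, f_hi = 1.0 - 1e-6;
  const double p_lo = 1e-9, p_hi = 1.0 - 1e-9;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_prev = -datum::inf;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    mat P = clamp(Q * F, p_lo, p_hi);           // n x L
    double ll = accu(Galt % log(P) + Gref % log1p(-P));
    if (!std::isfinite(ll))
      Rcpp::stop("non-finite log-likelihood at iteration %d", it + 1);
    trace.push_back(ll);
    if (it > 0 && ll - ll_prev < tol) { converged = true; break; }
    ll_prev = ll;

    mat Ralt = Galt / P;                        // zero stays zero
    mat Rref = Gref / (1.0 - P);
    mat Qn = Q % (Ralt * F.t() + Rref * (1.0 - F.t()));
    Qn.each_col() /= (2.0 * L_i);
    mat Ualt = Ralt.t() * Q;                    // L x K
    mat Uref = Rref.t() * Q;
    mat num = F.t() % Ualt;
    mat den = num + (1.0 - F.t()) % Uref;
    den.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
    F = clamp((num / den).t(), f_lo, f_hi);
    Q = Qn.each_col() / sum(Qn, 1);             // guard simplex drift
  }
  return Rcpp::List::create(
    Rcpp::Named("Q") = Q, Rcpp::Named("F") = F,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged);
}
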