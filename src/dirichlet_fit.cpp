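#include <Rcpp.h>
using namespace Rcpp;

// Inverse digamma: piecewise initializer then 5 Newton steps
// (exp(y)+0.5 for y >= -2.22, else -1/(y + Euler-Mascheroni)).
static double inv_digamma1(double y) {
  double x = (y >= -2.22) ? std::exp(y) + 0.5
                          : -1.0 / (y + 0.5772156649015329);
  for (int i = 0; i < 5; ++i)
    x -= (R::digamma(x) - y) / R::trigamma(x);
  return x;
}

// Fixed-point Dirichlet MLE sweep:
//   alpha_k <- invdigamma( digamma(alpha_0) + mean log x_k )
// status: 0 converged, 1 non-finite update, 2 alpha0 cap exceeded
// (degenerate data), 3 max_iter reached.
// [[Rcpp::export(name = ".fit_dirichlet_fp")]]
List fit_dirichlet_fp(NumericVector logp_bar, NumericVector init,
                      double tol, int max_iter, double alpha0_cap) {
  int K = logp_bar.size();
  NumericVector alpha = clone(init);
  int status = 3, iter = 0;
  double delta = R_PosInf;
  while (iter < max_iter) {
    ++iter;
    double a0 = 0.0;
    for (int k = 0; k < K; ++k) a0 += alpha[k];
    double psi_a0 = R::digamma(a0);
    double news = 0.0;
    delta = 0.0;
    NumericVector anew(K);
    for (int k = 0; k < K; ++k) {
      double a = inv_digamma1(psi_a0 + logp_bar[k]);
      if (!R_finite(a) || a <= 0.0) {
        return List::create(_["alpha"] = alpha, _["iterations"] = iter,
                            _["status"] = 1, _["delta"] = delta);
      }
      anew[k] = a;
      double d = std::fabs(a - alpha[k]) / alpha[k];
      if (d > delta) delta = d;
      news += a;
    }
    alpha = anew;
    if (news > alpha0_cap) {
      return List::create(_["alpha"] = alpha, _["iterations"] = iter,
                          _["status"] = 2, _["delta"] = delta);
    }
    if (delta < tol) { status = 0; break; }
  }
  return List::create(_["alpha"] = alpha, _["iterations"] = iter,
                      _["status"] = status, _["delta"] = delta);
}
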