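// Multivariate-normal variance-components likelihood, profiled over the
// fixed effects, evaluated family-by-family (block-diagonal covariance).
//
// Model per family f:  y_f ~ MVN(X_f beta, V_f),  V_f = sum_k sigma_k K_fk
// where the K_fk are the family's covariance kernels (locus IBD matrix Pi,
// twice-kinship 2*Phi, identity).  beta is profiled out jointly across
// families by GLS; the gradient uses the envelope identity at beta-hat:
//   d l / d sigma_k = -1/2 sum_f [ tr(V_f^-1 K_fk) - e_f' V_f^-1 K_fk V_f^-1 e_f ]

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List vc_loglik_cpp(List blocks, arma::vec sigma, bool grad = false) {
  const int nb = blocks.size();
  const int nk = sigma.n_elem;

  int p = -1, ntot = 0;
  double logdet = 0.0, q = 0.0;
  arma::mat A;   // X' V^-1 X
  arma::vec b;   // X' V^-1 y
  bool ok = true;

  for (int i = 0; i < nb && ok; ++i) {
    List bl = blocks[i];
    arma::vec y = as<arma::vec>(bl["y"]);
    arma::mat X = as<arma::mat>(bl["X"]);
    List Ks = bl["K"];
    const int m = y.n_elem;
    if (p < 0) { p = X.n_cols; A.zeros(p, p); b.zeros(p); }
    ntot += m;

    arma::mat V(m, m, arma::fill::zeros);
    for (int k = 0; k < nk; ++k)
      if (sigma[k] != 0.0) V += sigma[k] * as<arma::mat>(Ks[k]);

    arma::mat L;
    if (!arma::chol(L, V, "lower")) { ok = false; break; }
    logdet += 2.0 * arma::sum(arma::log(L.diag()));

    arma::vec wy = arma::solve(arma::trimatl(L), y);
    arma::mat wX = arma::solve(arma::trimatl(L), X);
    A += wX.t() * wX;
    b += wX.t() * wy;
    q += arma::dot(wy, wy);
  }

  if (!ok)
    return List::create(_["loglik"] = R_NegInf, _["ok"] = false);

  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::no_approx))
    return List::create(_["loglik"] = R_NegInf, _["ok"] = false);

  const double quad = q - arma::dot(beta, b);
  const double ll = -0.5 * (ntot * std::log(2.0 * M_PI) + logdet + quad);

  List out = List::create(_["loglik"] = ll, _["beta"] = beta,
                          _["XtViX"] = A, _["n"] = ntot, _["ok"] = true);

  if (grad) {
    arma::vec g(nk, arma::fill::zeros);
    for (int i = 0; i < nb; ++i) {
      List bl = blocks[i];
      arma::vec y = as<arma::vec>(bl["y"]);
      arma::mat X = as<arma::mat>(bl["X"]);
      List Ks = bl["K"];
      const int m = y.n_elem;

      arma::mat V(m, m, arma::fill::zeros);
      for (int k = 0; k < nk; ++k)
        if (sigma[k] != 0.0) V += sigma[k] * as<arma::mat>(Ks[k]);

      arma::mat Vinv = arma::inv_sympd(V);
      arma::vec e = y - X * beta;
      arma::vec u = Vinv * e;
      for (int k = 0; k < nk; ++k) {
        arma::mat K = as<arma::mat>(Ks[k]);
        g[k] += -0.5 * (arma::trace(Vinv * K) - arma::dot(u, K * u));
      }
    }
    out["gradient"] = g;
  }
  return out;
}
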