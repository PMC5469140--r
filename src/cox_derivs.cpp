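#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Partial log-likelihood, score and observed information for a Cox model
// with right-censored data and Efron (or Breslow) handling of ties.
//
// W   : n x p design matrix (fixed-effect columns followed by group
//       indicator columns when a frailty term is present)
// eta : n-vector linear predictor (W %*% theta); passed separately so the
//       caller can centre or offset it
//
// The linear predictor is centred internally before exponentiation, which
// leaves the partial likelihood and its derivatives unchanged but avoids
// overflow for large |eta|.
//
// For a death set D of size d at an event time, the Efron terms
//   sum_k (S1 - (k/d) S1D) / s0k          (score)
//   sum_k (S2 - (k/d) S2D) / s0k
//        - (S1 - (k/d) S1D)(...)' / s0k^2 (information)
// are accumulated through the scalar sums c0 = sum 1/s0k,
// c1 = sum (k/d)/s0k, d0 = sum 1/s0k^2, d1 = sum (k/d)/s0k^2,
// d2 = sum (k/d)^2/s0k^2, so no per-death matrix temporaries are formed.
// Only the upper triangle is accumulated (symmetrized at the end), and
// the per-subject rank-one updates skip zero entries, which makes the
// group-indicator block cheap.
//
// When derivs is false only the log-likelihood is returned (used during
// step-halving).
// [[Rcpp::export]]
List cox_derivs(const arma::vec& time, const arma::ivec& status,
                const arma::mat& W, const arma::vec& eta,
                const bool efron, const bool derivs) {
  const arma::uword n = W.n_rows;
  const arma::uword p = W.n_cols;
  arma::uvec ord = arma::sort_index(time, "descend");
  arma::vec etac = eta - eta.max();
  arma::vec rv = arma::exp(etac);

  double ll = 0.0;
  arma::vec grad(p, arma::fill::zeros);
  arma::mat hess(p, p, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  arma::vec S1D(p), sumw(p);
  arma::mat S2D(p, p);

  arma::uword i = 0;
  while (i < n) {
    const double t = time(ord(i));
    double S0D = 0.0, sum_eta = 0.0;
    int d = 0;
    if (p > 0 && derivs) { S1D.zeros(); sumw.zeros(); S2D.zeros(); }
    arma::uword j = i;
    while (j < n && time(ord(j)) == t) {
      const arma::uword k = ord(j);
      const double rk = rv(k);
      const bool dead = status(k) == 1;
      S0 += rk;
      if (dead) { ++d; S0D += rk; sum_eta += etac(k); }
      if (p > 0 && derivs) {
        for (arma::uword a = 0; a < p; ++a) {
          const double wa = W(k, a);
          if (wa == 0.0) continue;
          S1(a) += rk * wa;
          if (dead) { S1D(a) += rk * wa; sumw(a) += wa; }
          {
            const double rwa = rk * wa;
            for (arma::uword b = a; b < p; ++b) {
              const double wb = W(k, b);
              if (wb == 0.0) continue;
              S2(a, b) += rwa * wb;
              if (dead) S2D(a, b) += rwa * wb;
            }
          }
        }
      }
      ++j;
    }
    if (d > 0) {
      ll += sum_eta;
      double c0 = 0.0, c1 = 0.0, d0 = 0.0, d1 = 0.0, d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double f = efron ? static_cast<double>(k) / d : 0.0;
        const double s0k = S0 - f * S0D;
        ll -= std::log(s0k);
        c0 += 1.0 / s0k;
        c1 += f / s0k;
        d0 += 1.0 / (s0k * s0k);
        d1 += f / (s0k * s0k);
        d2 += f * f / (s0k * s0k);
      }
      if (p > 0 && derivs) {
        grad += sumw - c0 * S1 + c1 * S1D;
        {
          if (c1 == 0.0) {  // untied or Breslow: S1D/S2D terms vanish
            for (arma::uword a = 0; a < p; ++a)
              for (arma::uword b = a; b < p; ++b)
                hess(a, b) += c0 * S2(a, b) - d0 * S1(a) * S1(b);
          } else {
            for (arma::uword a = 0; a < p; ++a)
              for (arma::uword b = a; b < p; ++b)
                hess(a, b) += c0 * S2(a, b) - c1 * S2D(a, b)
                  - d0 * S1(a) * S1(b)
                  + d1 * (S1(a) * S1D(b) + S1D(a) * S1(b))
                  - d2 * S1D(a) * S1D(b);
          }
        }
      }
    }
    i = j;
  }
  if (!derivs)
    return List::create(_["loglik"] = ll);
  hess = arma::symmatu(hess);
  return List::create(_["loglik"] = ll, _["grad"] = grad, _["hess"] = hess);
}
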