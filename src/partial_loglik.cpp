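// Log-partial likelihood for time-varying coefficients, Breslow ties,
// accumulated event time by event time through the Kronecker structure
// x_i(t) = z_i (x) B(t): per event time only the at-risk rows' p-vector z
// and the K-vector B(t_m) are combined; the n x pK expanded design is never
// materialized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Z        : n_s x p covariate rows of ONE stratum, sorted by decreasing time
//            (so the risk set of event time m is rows 0 .. risk_n[m]-1)
// theta    : p x K basis-coefficient matrix
// B        : M x K basis values at the stratum's distinct event times (ascending)
// risk_n   : M, size of the at-risk set at each event time
// tie_ptr  : M+1 offsets into tie_idx (0-based)
// tie_idx  : row indices (0-based, into Z) of subjects failing at each event time
// want     : 0 = value, 1 = + gradient, 2 = + Hessian, 3 = + score information J
//
// Flattening of vec(theta) is covariate-major: the K coefficients of
// covariate 1 first, then covariate 2, etc.  Gradient is returned in p x K
// matrix form; Hessian and J in pK x pK with that ordering (kron(p-block, K-block)).
// [[Rcpp::export]]
List stratum_loglik_cpp(const arma::mat& Z, const arma::mat& theta,
                        const arma::mat& B, const arma::ivec& risk_n,
                        const arma::ivec& tie_ptr, const arma::ivec& tie_idx,
                        const int want) {
  const arma::uword p = Z.n_cols, K = theta.n_cols, M = B.n_rows;
  const arma::uword pK = p * K;
  double ll = 0.0;
  arma::mat G(p, K, arma::fill::zeros);
  arma::mat H(want >= 2 ? pK : 0, want >= 2 ? pK : 0, arma::fill::zeros);
  arma::mat J(want >= 3 ? pK : 0, want >= 3 ? pK : 0, arma::fill::zeros);

  for (arma::uword m = 0; m < M; ++m) {
    const arma::uword nm = (arma::uword) risk_n[m];
    const arma::rowvec b = B.row(m);
    const arma::vec a = theta * b.t();              // p, so eta_i = z_i' a
    arma::vec eta;
    if (nm == Z.n_rows) {
      eta = Z * a;
    } else {
      eta = Z.rows(0, nm - 1) * a;
    }
    const double c = eta.max();                     // log-sum-exp shift
    const arma::vec w = arma::exp(eta - c);
    const double S0 = arma::accu(w);
    const int d = tie_ptr[m + 1] - tie_ptr[m];

    // event terms
    arma::vec zsum(p, arma::fill::zeros);
    for (int q = tie_ptr[m]; q < tie_ptr[m + 1]; ++q) {
      const arma::rowvec zi = Z.row((arma::uword) tie_idx[q]);
      ll += arma::dot(zi.t(), a);
      if (want >= 1) zsum += zi.t();
    }
    ll -= d * (std::log(S0) + c);

    if (want >= 1) {
      arma::vec zbar;
      if (nm == Z.n_rows) {
        zbar = (Z.t() * w) / S0;
      } else {
        zbar = (Z.rows(0, nm - 1).t() * w) / S0;
      }
      const arma::vec gz = zsum - d * zbar;         // p
      const arma::mat Gm = gz * b;                  // p x K
      G += Gm;
      if (want >= 2) {
        arma::mat Szz(p, p, arma::fill::zeros);
        if (nm == Z.n_rows) {
          Szz = Z.t() * (Z.each_col() % w);
        } else {
          const arma::mat Zsub = Z.rows(0, nm - 1);
          Szz = Zsub.t() * (Zsub.each_col() % w);
        }
        const arma::mat Czz = Szz / S0 - zbar * zbar.t();   // weighted covariance
        H -= d * arma::kron(Czz, b.t() * b);
        if (want >= 3) {
          const arma::vec u = arma::vectorise(Gm.t());      // covariate-major
          J += u * u.t();
        }
      }
    }
  }

  List out = List::create(Named("loglik") = ll);
  if (want >= 1) out["gradient"] = G;
  if (want >= 2) out["hessian"] = H;
  if (want >= 3) out["score_info"] = J;
  return out;
}
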