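#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Decoupled conditional update of the genetic effects on the eigenbasis of
// the genomic relationship matrix: for eigen-index i the J-vector of rotated
// effects has precision Kinv / d_i + Rinv and mean Sigma * Rinv * yt_i.
// Uses R's RNG so chains are reproducible from set.seed().
// Returns both the draw and the conditional mean (the latter feeds the
// Rao-Blackwellised point predictions).
// [[Rcpp::export(name = ".sample_u_rot_cpp")]]
List sample_u_rot_cpp(const arma::mat& Yt, const arma::vec& d,
                      const arma::mat& Kinv, const arma::mat& Rinv) {
  const int n = Yt.n_rows, J = Yt.n_cols;
  arma::mat Ut(n, J), Mt(n, J);
  arma::vec z(J);
  for (int i = 0; i < n; ++i) {
    arma::mat prec = Kinv / d(i) + Rinv;
    arma::mat cholU;
    // rare near-singular sweeps (extreme K or R draws) get a ridge so the
    // factorisation and back-substitutions always go through
    bool ok = arma::chol(cholU, prec);
    int tries = 0;
    while ((!ok || cholU.diag().min() < 1e-12 * cholU.diag().max()) &&
           tries < 10) {
      prec.diag() += 1e-8 * (arma::trace(prec) / J) + 1e-12;
      ok = arma::chol(cholU, prec);
      ++tries;
    }
    arma::vec rhs = Rinv * Yt.row(i).t();
    arma::vec mu = arma::solve(arma::trimatu(cholU),
                               arma::solve(arma::trimatl(cholU.t()), rhs,
                                           arma::solve_opts::fast),
                               arma::solve_opts::fast);
    for (int j = 0; j < J; ++j) z(j) = norm_rand();
    Mt.row(i) = mu.t();
    Ut.row(i) = (mu + arma::solve(arma::trimatu(cholU), z,
                                  arma::solve_opts::fast)).t();
  }
  return List::create(Named("Ut") = Ut, Named("Mt") = Mt);
}
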