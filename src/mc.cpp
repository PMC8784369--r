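// Monte-Carlo core for registration error simulation: per repetition,
// perturb both sides of a fiducial correspondence with localization noise,
// refit the least-squares rigid transform in closed form, and record the
// displacement at a target point plus the squared FRE.  Uses R's RNG so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Closed-form rigid fit of X (moving, N x 3) onto Y (fixed, N x 3):
// Y ~ X * R.t() + t.  Reflection corrected via the smallest singular vector.
static void fit_rigid(const arma::mat& X, const arma::mat& Y,
                      arma::mat33& R, arma::rowvec& t) {
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx, Yc = Y.each_row() - cy;
  arma::mat33 H = Xc.t() * Yc;
  arma::mat33 U, V;
  arma::vec3 s;
  arma::svd(U, s, V, H);
  arma::mat33 D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = cy - cx * R.t();
}

// [[Rcpp::export]]
List cpp_mc_tre(const arma::mat& fids, const arma::vec& target,
                const arma::mat& chol_moving, const arma::mat& chol_fixed,
                int reps) {
  const int n = fids.n_rows;
  arma::mat disp(reps, 3);
  arma::vec fre2(reps);
  arma::mat Em(n, 3), Ef(n, 3);
  arma::rowvec tg = target.t();

  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) {
        Em(i, j) = norm_rand();
        Ef(i, j) = norm_rand();
      }
    arma::mat X = fids + Em * chol_moving;   // chol upper: z * U == L.t()*? (see R side)
    arma::mat Y = fids + Ef * chol_fixed;
    arma::mat33 R;
    arma::rowvec t;
    fit_rigid(X, Y, R, t);
    arma::mat res = Y - X * R.t();
    res.each_row() -= t;
    fre2(r) = arma::accu(res % res) / n;
    disp.row(r) = tg * R.t() + t - tg;
  }
  return List::create(_["displacements"] = disp, _["fre2"] = fre2);
}

// [[Rcpp::export]]
List cpp_fit_rigid(const arma::mat& X, const arma::mat& Y) {
  arma::mat33 R;
  arma::rowvec t;
  fit_rigid(X, Y, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t.t());
}
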