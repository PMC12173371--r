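// Eigen-rotated computations for the Kronecker-covariance model
//   cov(vec Y) = G (x) K + R (x) I.
// After rotating rows of the column-centered Y by the eigenvectors of K,
// rows are independent with covariance S_m = d_m G + R; everything below
// works row-wise in that coordinate system.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat safe_inv_sympd(const mat& S) {
  mat Si;
  if (!inv_sympd(Si, S)) {
    mat Sj = S + eye(S.n_rows, S.n_cols) * (1e-8 * trace(S) + 1e-12);
    Si = inv_sympd(Sj);
  }
  return Si;
}

// EM for (G, R): maximizes the likelihood of rotated rows Yt with
// covariance d_m G + R. Rows with d_m ~ 0 carry no genetic information and
// are excluded from the G update denominator.
// [[Rcpp::export(name = ".em_kron_cpp")]]
Rcpp::List em_kron_cpp(const arma::mat& Yt, const arma::vec& d, arma::mat G, arma::mat R,
                       double tol, int maxit) {
  const uword n = Yt.n_rows;
  const uword t = Yt.n_cols;
  uvec pos = find(d > 1e-10);
  double n_pos = std::max((double)pos.n_elem, 1.0);
  std::vector<double> ll_trace;
  bool converged = false;

  for (int iter = 0; iter < maxit; ++iter) {
    mat Gn(t, t, fill::zeros), Rn(t, t, fill::zeros);
    double ll = 0.0;
    for (uword m = 0; m < n; ++m) {
      mat S = d(m) * G + R;
      mat Si = safe_inv_sympd(S);
      double ld, sign;
      log_det(ld, sign, S);
      vec y = Yt.row(m).t();
      vec z = Si * y;
      ll += -0.5 * ld - 0.5 * dot(y, z);
      mat GS = d(m) * G * Si;  // zero matrix when d_m = 0
      vec u = GS * y;
      vec e = y - u;
      mat Ve = R - R * Si * R;
      Rn += e * e.t() + Ve;
      if (d(m) > 1e-10) {
        mat Vu = d(m) * G - GS * (d(m) * G);
        Gn += (u * u.t() + Vu) / d(m);
      }
    }
    ll_trace.push_back(ll);
    G = (Gn + Gn.t()) / (2.0 * n_pos);
    R = (Rn + Rn.t()) / (2.0 * n);
    size_t k = ll_trace.size();
    if (k > 1 && std::abs(ll_trace[k - 1] - ll_trace[k - 2]) < tol) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("G") = G, Rcpp::Named("R") = R,
    Rcpp::Named("logLik") = ll_trace,
    Rcpp::Named("converged") = converged);
}

// Row-wise solve A_m = (d_m G + R)^{-1} y_m for the BLUP linear system.
// [[Rcpp::export(name = ".kron_rowsolve_cpp")]]
arma::mat kron_rowsolve_cpp(const arma::mat& Yt, const arma::vec& d, const arma::mat& G,
                      const arma::mat& R) {
  const uword n = Yt.n_rows;
  mat A(n, Yt.n_cols);
  for (uword m = 0; m < n; ++m) {
    mat Si = safe_inv_sympd(d(m) * G + R);
    A.row(m) = (Si * Yt.row(m).t()).t();
  }
  return A;
}

// Log-likelihood and analytic gradient for direct maximization over
// Cholesky factors G = Lg Lg', R = Lr Lr'. par packs the lower triangles
// of Lg then Lr, column-major.
// An optional inverse-Wishart penalty on R (scale Sp, degrees nu) keeps
// the residual covariance away from the zero boundary, emulating the
// regularization a Bayesian multivariate mixed model applies; pass nu = 0
// to disable.
// [[Rcpp::export(name = ".kron_ml_obj_cpp")]]
Rcpp::List kron_ml_obj_cpp(const arma::vec& par, const arma::mat& Yt,
                           const arma::vec& d, const arma::mat& Sp,
                           double nu) {
  const uword t = Yt.n_cols;
  const uword n = Yt.n_rows;
  const uword ntri = t * (t + 1) / 2;
  mat Lg(t, t, fill::zeros), Lr(t, t, fill::zeros);
  uword k = 0;
  for (uword j = 0; j < t; ++j)
    for (uword i = j; i < t; ++i) Lg(i, j) = par(k++);
  for (uword j = 0; j < t; ++j)
    for (uword i = j; i < t; ++i) Lr(i, j) = par(k++);
  mat G = Lg * Lg.t();
  mat R = Lr * Lr.t();

  double ll = 0.0;
  mat dG(t, t, fill::zeros), dR(t, t, fill::zeros);
  const mat ridge = eye(t, t) * 1e-8;  // constant: keeps obj/grad consistent
  for (uword m = 0; m < n; ++m) {
    mat S = d(m) * G + R + ridge;
    mat Si = safe_inv_sympd(S);
    double ld, sign;
    log_det(ld, sign, S);
    vec y = Yt.row(m).t();
    vec z = Si * y;
    ll += -0.5 * ld - 0.5 * dot(y, z);
    mat M = Si - z * z.t();  // d(-ll)/dS * 2
    dG += -0.5 * d(m) * M;
    dR += -0.5 * M;
  }
  if (nu > 0) {
    mat Ri = safe_inv_sympd(R + ridge);
    double ldr, sgn;
    log_det(ldr, sgn, R + ridge);
    ll += -0.5 * (nu + t + 1.0) * ldr - 0.5 * trace(Sp * Ri);
    dR += -0.5 * (nu + t + 1.0) * Ri + 0.5 * Ri * Sp * Ri;
  }
  mat gLg = 2.0 * dG * Lg;
  mat gLr = 2.0 * dR * Lr;
  vec grad(2 * ntri);
  k = 0;
  for (uword j = 0; j < t; ++j)
    for (uword i = j; i < t; ++i) grad(k++) = gLg(i, j);
  for (uword j = 0; j < t; ++j)
    for (uword i = j; i < t; ++i) grad(k++) = gLr(i, j);
  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("grad") = grad);
}
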