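// Compiled core of the Metropolis-within-Gibbs sampler for the quadratic
// transfer-distance model. One call runs one chain; all randomness comes
// from R's RNG so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double rinvgamma_rate(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// X ~ N(mean, sd) truncated to (-inf, 0]; log-scale inverse CDF keeps the
// far tail stable.
static double rtnorm_upper0_1(double mean, double sd) {
  double alpha = (0.0 - mean) / sd;
  double lp = std::log(R::runif(0.0, 1.0)) +
    R::pnorm(alpha, 0.0, 1.0, 1, 1);
  return mean + sd * R::qnorm(lp, 0.0, 1.0, 1, 1);
}

// Collapsed target for h_i: the curvature a_i ~ N-(0,1) is integrated out
// in closed form (Gaussian integral against a truncated normal), which
// removes the a -> 0, h -> infinity ridge that appears when the
// transfer signal is weak. cross(h) and quart(h) are the h-polynomials
// sum r_k (x_k - h)^2 and sum (x_k - h)^4 built from static moments.
struct HTarget {
  double ve, mu, sh2, s0, s1, s2, m1, m2, m3, m4, n;
  bool constrain;
  double operator()(double hh) const {
    double cross = s2 - 2.0 * hh * s1 + hh * hh * s0;
    double quart = m4 - 4.0 * hh * m3 + 6.0 * hh * hh * m2 -
      4.0 * hh * hh * hh * m1 + hh * hh * hh * hh * n;
    double A = quart / ve + 1.0;       // posterior precision of a
    double B = cross / ve;             // linear coefficient
    double lp = 0.5 * B * B / A - 0.5 * std::log(A);
    if (constrain) {
      // mass of the a <= 0 half of the Gaussian
      lp += R::pnorm(-B / std::sqrt(A), 0.0, 1.0, 1, 1);
    }
    return lp - (hh - mu) * (hh - mu) / sh2;
  }
};

// Scalar slice sampler (stepping-out and shrinkage).
static double slice1(double x0, const HTarget& f, double w) {
  double f0 = f(x0);
  if (!std::isfinite(f0)) return x0;
  double y = f0 - R::exp_rand();
  double L = x0 - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  for (int k = 0; k < 50; ++k) {
    double fl = f(L);
    if (!std::isfinite(fl) || fl <= y) break;
    L -= w;
  }
  for (int k = 0; k < 50; ++k) {
    double fr = f(Rr);
    if (!std::isfinite(fr) || fr <= y) break;
    Rr += w;
  }
  for (int rep = 0; rep < 200; ++rep) {
    double x1 = R::runif(L, Rr);
    double f1 = f(x1);
    if (std::isfinite(f1) && f1 > y) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// [[Rcpp::export(name = ".transfer_chain_cpp")]]
arma::mat transfer_chain_cpp(const arma::vec& y, const arma::vec& x,
                             const arma::vec& X,
                             const arma::ivec& ti,  // 1-based trial index
                             const arma::ivec& gi,  // 1-based group index
                             const arma::ivec& g_trial,
                             const arma::vec& n_i, const arma::vec& n_g,
                             int iterations, int warmup, bool constrain,
                             arma::vec cg, arma::vec a, arma::vec h,
                             double mu_c, double mu_h, double beta_h,
                             double sigma_c, double sigma_h,
                             arma::vec sigma_e) {
  const uword n = y.n_elem;
  const uword I = X.n_elem;
  const uword Gn = cg.n_elem;
  const double nu_t = 3.0, A_t = 2.5;
  double aux_c = 1.0, aux_h = 1.0;
  vec aux_e(I, fill::ones);
  const double prior_prec_mu_c = 1.0, prior_prec_mu_h = 1.0;
  const double prior_prec_beta = 1.0 / 9.0;

  // static per-trial x-moments
  vec m1(I, fill::zeros), m2(I, fill::zeros), m3(I, fill::zeros),
      m4(I, fill::zeros);
  for (uword k = 0; k < n; ++k) {
    uword i = ti(k) - 1;
    double xv = x(k);
    m1(i) += xv; m2(i) += xv * xv; m3(i) += xv * xv * xv;
    m4(i) += xv * xv * xv * xv;
  }
  vec step_h(I, fill::value(0.3));
  vec h_prev = h;

  const int keep = iterations - warmup;
  const uword P = 5 + 3 * I + Gn;
  mat out(keep, P);

  vec ve(I), sum_rc(Gn), A_i(I), B_i(I), s0(I), s1(I), s2(I), ssr(I);
  for (int it = 1; it <= iterations; ++it) {
    ve = sigma_e % sigma_e;

    // group maxima c_g
    sum_rc.zeros();
    for (uword k = 0; k < n; ++k) {
      uword i = ti(k) - 1;
      double d = x(k) - h(i);
      sum_rc(gi(k) - 1) += y(k) - a(i) * d * d;
    }
    for (uword g = 0; g < Gn; ++g) {
      double prec = n_g(g) / ve(g_trial(g) - 1) + 1.0 / (sigma_c * sigma_c);
      double mg = (sum_rc(g) / ve(g_trial(g) - 1) +
                   mu_c / (sigma_c * sigma_c)) / prec;
      cg(g) = R::rnorm(mg, 1.0 / std::sqrt(prec));
    }

    // mu_c
    {
      double prec = Gn / (sigma_c * sigma_c) + prior_prec_mu_c;
      mu_c = R::rnorm(accu(cg) / (sigma_c * sigma_c) / prec,
                      1.0 / std::sqrt(prec));
    }

    // sigma_c (auxiliary-variable Gibbs for the half-t prior)
    {
      double ssq = accu(square(cg - mu_c));
      double s2c = rinvgamma_rate((nu_t + Gn) / 2.0,
                                  nu_t / aux_c + ssq / 2.0);
      sigma_c = std::sqrt(s2c);
      aux_c = rinvgamma_rate((nu_t + 1.0) / 2.0,
                             nu_t / s2c + 1.0 / (A_t * A_t));
    }

    // residual moments for the h and a updates
    s0.zeros(); s1.zeros(); s2.zeros();
    for (uword k = 0; k < n; ++k) {
      uword i = ti(k) - 1;
      double ra = y(k) - cg(gi(k) - 1);
      s0(i) += ra; s1(i) += ra * x(k); s2(i) += ra * x(k) * x(k);
    }

    // optima h_i: slice sampling on the collapsed (a integrated out) target
    for (uword i = 0; i < I; ++i) {
      HTarget f;
      f.ve = ve(i);
      f.mu = mu_h + beta_h * X(i);
      f.sh2 = 2.0 * sigma_h * sigma_h;
      f.s0 = s0(i); f.s1 = s1(i); f.s2 = s2(i);
      f.m1 = m1(i); f.m2 = m2(i); f.m3 = m3(i); f.m4 = m4(i);
      f.n = n_i(i);
      f.constrain = constrain;
      h(i) = slice1(h(i), f, step_h(i));
    }
    if (it <= warmup) {
      for (uword i = 0; i < I; ++i) {
        step_h(i) = std::max(0.9 * step_h(i) +
                             0.1 * std::fabs(h(i) - h_prev(i)), 1e-4);
        h_prev(i) = h(i);
      }
    }

    // curvatures a_i | h_i (conjugate, from the same moments)
    for (uword i = 0; i < I; ++i) {
      double hh = h(i);
      double cross = s2(i) - 2.0 * hh * s1(i) + hh * hh * s0(i);
      double quart = m4(i) - 4.0 * hh * m3(i) + 6.0 * hh * hh * m2(i) -
        4.0 * hh * hh * hh * m1(i) + hh * hh * hh * hh * n_i(i);
      double Ai = quart / ve(i) + 1.0;
      double mi = cross / ve(i) / Ai;
      double si = 1.0 / std::sqrt(Ai);
      a(i) = constrain ? rtnorm_upper0_1(mi, si) : R::rnorm(mi, si);
    }

    // (mu_h, beta_h): bivariate conjugate regression of h on (1, X)
    {
      double sh2 = sigma_h * sigma_h;
      double p11 = I / sh2 + prior_prec_mu_h;
      double p12 = accu(X) / sh2;
      double p22 = accu(square(X)) / sh2 + prior_prec_beta;
      double b1 = accu(h) / sh2;
      double b2 = accu(h % X) / sh2;
      double det = p11 * p22 - p12 * p12;
      double mb1 = (p22 * b1 - p12 * b2) / det;
      double mb2 = (p11 * b2 - p12 * b1) / det;
      // Cholesky of the covariance (inverse precision)
      double c11 = p22 / det, c12 = -p12 / det, c22 = p11 / det;
      double l11 = std::sqrt(c11);
      double l21 = c12 / l11;
      double l22 = std::sqrt(c22 - l21 * l21);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      mu_h = mb1 + l11 * z1;
      beta_h = mb2 + l21 * z1 + l22 * z2;
    }

    // sigma_h: centered conjugate update ...
    {
      double ssq = 0.0;
      for (uword i = 0; i < I; ++i) {
        double r = h(i) - mu_h - beta_h * X(i);
        ssq += r * r;
      }
      double s2h = rinvgamma_rate((nu_t + I) / 2.0,
                                  nu_t / aux_h + ssq / 2.0);
      sigma_h = std::sqrt(s2h);
    }
    // ... interwoven with a non-centered (ancillary) move: holding
    // eta_i = (h_i - mu_h - beta_h X_i) / sigma_h fixed, slice-sample
    // log sigma_h against the data likelihood and the marginal half-t
    // prior, letting the optima travel with the scale. This breaks the
    // funnel that traps sigma_h near zero when the h_i sit exactly on
    // the regression line.
    if (sigma_h > 1e-12) {
      vec eta(I), muh(I);
      for (uword i = 0; i < I; ++i) {
        muh(i) = mu_h + beta_h * X(i);
        eta(i) = (h(i) - muh(i)) / sigma_h;
      }
      auto logtarget = [&](double ls) {
        double s = std::exp(ls);
        double lp = -(nu_t + 1.0) / 2.0 *
          std::log1p((s / A_t) * (s / A_t) / nu_t) + ls;  // prior + Jacobian
        for (uword i = 0; i < I; ++i) {
          double hh = muh(i) + s * eta(i);
          double cross = s2(i) - 2.0 * hh * s1(i) + hh * hh * s0(i);
          double quart = m4(i) - 4.0 * hh * m3(i) + 6.0 * hh * hh * m2(i) -
            4.0 * hh * hh * hh * m1(i) + hh * hh * hh * hh * n_i(i);
          lp += -(-2.0 * a(i) * cross + a(i) * a(i) * quart) /
            (2.0 * ve(i));
        }
        return lp;
      };
      double ls0 = std::log(sigma_h);
      double f0 = logtarget(ls0);
      if (std::isfinite(f0)) {
        double yslice = f0 - R::exp_rand();
        double L = ls0 - 0.7 * R::runif(0.0, 1.0);
        double Rr = L + 0.7;
        for (int k = 0; k < 30 && logtarget(L) > yslice; ++k) L -= 0.7;
        for (int k = 0; k < 30 && logtarget(Rr) > yslice; ++k) Rr += 0.7;
        for (int rep = 0; rep < 100; ++rep) {
          double ls1 = R::runif(L, Rr);
          if (logtarget(ls1) > yslice) {
            sigma_h = std::exp(ls1);
            for (uword i = 0; i < I; ++i) h(i) = muh(i) + sigma_h * eta(i);
            break;
          }
          if (ls1 < ls0) L = ls1; else Rr = ls1;
        }
      }
    }
    aux_h = rinvgamma_rate((nu_t + 1.0) / 2.0,
                           nu_t / (sigma_h * sigma_h) + 1.0 / (A_t * A_t));

    // per-trial residual scales
    ssr.zeros();
    for (uword k = 0; k < n; ++k) {
      uword i = ti(k) - 1;
      double d = x(k) - h(i);
      double r = y(k) - cg(gi(k) - 1) - a(i) * d * d;
      ssr(i) += r * r;
    }
    for (uword i = 0; i < I; ++i) {
      double s2e = rinvgamma_rate((nu_t + n_i(i)) / 2.0,
                                  nu_t / aux_e(i) + ssr(i) / 2.0);
      sigma_e(i) = std::sqrt(s2e);
      aux_e(i) = rinvgamma_rate((nu_t + 1.0) / 2.0,
                                nu_t / s2e + 1.0 / (A_t * A_t));
    }

    if (it > warmup) {
      uword r = it - warmup - 1;
      out(r, 0) = mu_c; out(r, 1) = mu_h; out(r, 2) = beta_h;
      out(r, 3) = sigma_c; out(r, 4) = sigma_h;
      for (uword i = 0; i < I; ++i) out(r, 5 + i) = a(i);
      for (uword i = 0; i < I; ++i) out(r, 5 + I + i) = h(i);
      for (uword i = 0; i < I; ++i) out(r, 5 + 2 * I + i) = sigma_e(i);
      for (uword g = 0; g < Gn; ++g) out(r, 5 + 3 * I + g) = cg(g);
    }
  }
  return out;
}
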