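// Marginal log-likelihood of a binomial probit GLMM with a 2-D random effect
// (per-observer intercept + contrast slope), evaluated by adaptive
// Gauss-Hermite quadrature on the standardized scale b = L u, u ~ N(0, I).
//
// The standardized parameterization keeps the inner problem well conditioned
// for any Cholesky factor L, including singular and exactly-zero L: at L = 0
// the integrand is Gaussian in u and the quadrature is exact, so the marginal
// likelihood collapses to the plain probit GLM likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG_SQRT_2PI = 0.9189385332046727;

// log Phi(eta); erfc-based in the bulk, R's tail-accurate pnorm beyond
static inline double log_Phi(double eta) {
  if (std::fabs(eta) < 8.0) {
    return std::log(0.5 * std::erfc(-eta * M_SQRT1_2));
  }
  return R::pnorm(eta, 0.0, 1.0, 1, 1);
}

// binomial probit log-likelihood of one cell
static inline double cell_ll(double eta, double y, double n) {
  return y * log_Phi(eta) + (n - y) * log_Phi(-eta);
}

// adds the cell's log-lik and its first/second derivatives wrt eta
static inline void cell_derivs(double eta, double y, double n,
                               double &ll, double &g, double &h) {
  const double logP = log_Phi(eta), log1P = log_Phi(-eta);
  const double logd = -0.5 * eta * eta - LOG_SQRT_2PI;
  const double r1 = std::exp(logd - logP);    // phi/Phi
  const double r2 = std::exp(logd - log1P);   // phi/(1-Phi)
  ll += y * logP + (n - y) * log1P;
  g  += y * r1 - (n - y) * r2;
  h  += y * (-eta * r1 - r1 * r1) + (n - y) * (eta * r2 - r2 * r2);
}

// penalized objective h(u) = loglik(u) - u'u/2 for one observer
static inline double pen_obj(const double *xb, const double *zl1,
                             const double *zl2, const double *y,
                             const double *n, const uword m, const vec &u) {
  double ll = 0.0;
  for (uword j = 0; j < m; ++j) {
    ll += cell_ll(xb[j] + zl1[j] * u(0) + zl2[j] * u(1), y[j], n[j]);
  }
  return ll - 0.5 * dot(u, u);
}

static inline double pen_obj_derivs(const double *xb, const double *zl1,
                                    const double *zl2, const double *y,
                                    const double *n, const uword m,
                                    const vec &u, vec &grad, mat &negH) {
  double ll = 0.0;
  grad.zeros(2);
  negH.eye(2, 2);
  for (uword j = 0; j < m; ++j) {
    double eta = xb[j] + zl1[j] * u(0) + zl2[j] * u(1);
    double g = 0.0, h = 0.0;
    cell_derivs(eta, y[j], n[j], ll, g, h);
    grad(0) += g * zl1[j];
    grad(1) += g * zl2[j];
    negH(0, 0) -= h * zl1[j] * zl1[j];
    negH(0, 1) -= h * zl1[j] * zl2[j];
    negH(1, 1) -= h * zl2[j] * zl2[j];
  }
  negH(1, 0) = negH(0, 1);
  grad -= u;
  return ll - 0.5 * dot(u, u);
}

// [[Rcpp::export]]
double agq_loglik_cpp(const arma::vec &beta, const arma::vec &lvec,
                      const arma::mat &X, const arma::mat &Z,
                      const arma::uvec &obs_id,
                      const arma::vec &y, const arma::vec &n,
                      const arma::vec &ghz, const arma::vec &ghw) {
  const uword N = X.n_rows;
  mat L(2, 2, fill::zeros);
  L(0, 0) = lvec(0); L(1, 0) = lvec(1); L(1, 1) = lvec(2);
  const vec xb = X * beta;
  const mat ZL = Z * L;
  const uword nq = ghz.n_elem;
  const vec lghw = log(ghw);
  const double LOG2PI = 2.0 * LOG_SQRT_2PI;

  double total = 0.0;
  uword r0 = 0;
  while (r0 < N) {
    uword r1 = r0;
    while (r1 + 1 < N && obs_id(r1 + 1) == obs_id(r0)) ++r1;
    const uword m = r1 - r0 + 1;
    const double *xbi = xb.memptr() + r0;
    const double *zl1 = ZL.colptr(0) + r0;
    const double *zl2 = ZL.colptr(1) + r0;
    const double *yi = y.memptr() + r0;
    const double *ni = n.memptr() + r0;

    // inner Newton for the conditional mode of u
    vec u(2, fill::zeros), grad(2), step(2), unew(2);
    mat negH(2, 2);
    double f = pen_obj_derivs(xbi, zl1, zl2, yi, ni, m, u, grad, negH);
    for (int it = 0; it < 40; ++it) {
      if (dot(grad, grad) < 1e-10) break;
      step = solve(negH, grad, solve_opts::fast);
      double t = 1.0;
      double fnew;
      for (int halvings = 0; halvings < 30; ++halvings) {
        unew = u + t * step;
        fnew = pen_obj(xbi, zl1, zl2, yi, ni, m, unew);
        if (fnew >= f - 1e-12) break;
        t *= 0.5;
      }
      u = unew;
      f = pen_obj_derivs(xbi, zl1, zl2, yi, ni, m, u, grad, negH);
    }

    // adaptive rescaling: M = -Hessian at mode, C = R^{-1} with M = R'R
    const double m11 = negH(0, 0), m12 = negH(0, 1), m22 = negH(1, 1);
    const double rr11 = std::sqrt(m11);
    const double rr12 = m12 / rr11;
    const double rr22 = std::sqrt(std::max(m22 - rr12 * rr12, 1e-12));
    const double logdetC = -std::log(rr11) - std::log(rr22);
    // C = R^{-1}, upper triangular
    const double c11 = 1.0 / rr11, c12 = -rr12 / (rr11 * rr22), c22 = 1.0 / rr22;

    double obs_ll;
    if (nq == 1) {             // Laplace approximation
      obs_ll = f + logdetC;    // -log(2pi) + log(2pi) |M|^{-1/2} e^{h}
    } else {
      // tensor quadrature: u = u_hat + sqrt(2) * C * z
      const double s2 = std::sqrt(2.0);
      double smax = -datum::inf;
      vec svals(nq * nq);
      vec un(2);
      uword idx = 0;
      for (uword k = 0; k < nq; ++k) {
        for (uword l = 0; l < nq; ++l) {
          un(0) = u(0) + s2 * (c11 * ghz(k) + c12 * ghz(l));
          un(1) = u(1) + s2 * (c22 * ghz(l));
          double s = pen_obj(xbi, zl1, zl2, yi, ni, m, un) +
                     ghz(k) * ghz(k) + ghz(l) * ghz(l) + lghw(k) + lghw(l);
          svals(idx++) = s;
          if (s > smax) smax = s;
        }
      }
      double acc = 0.0;
      for (uword t = 0; t < svals.n_elem; ++t) acc += std::exp(svals(t) - smax);
      obs_ll = -LOG2PI + std::log(2.0) + logdetC + smax + std::log(acc);
    }
    total += obs_ll;
    r0 = r1 + 1;
  }
  return total;
}

// Negative marginal log-likelihood over theta = c(beta, l11, l21, l22),
// the objective handed to the outer optimizer.
// [[Rcpp::export]]
double agq_negloglik_cpp(const arma::vec &theta,
                         const arma::mat &X, const arma::mat &Z,
                         const arma::uvec &obs_id,
                         const arma::vec &y, const arma::vec &n,
                         const arma::vec &ghz, const arma::vec &ghw) {
  const uword p = X.n_cols;
  vec beta = theta.head(p);
  vec lvec = theta.tail(3);
  double ll = agq_loglik_cpp(beta, lvec, X, Z, obs_id, y, n, ghz, ghw);
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
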