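// Unconstrained-scale log posterior and analytic gradient for the
// hierarchical Student-t regression (model 1) and its distributional
// location-scale extension (model 2).
//
// Unconstrained layout, model 1 (33):
//   [b0, b(13), z_edu(6), z_occ(9), log_sd_edu, log_sd_occ, log_sigma,
//    log(nu - nu_lower)]
// model 2 (63):
//   [b0, b(13), z_edu(6), z_occ(9), log_sd_edu, log_sd_occ,
//    g0, g(13), zv_edu(6), zv_occ(9), log_sd_v_edu, log_sd_v_occ,
//    log(nu - nu_lower)]
//
// Group deviations are non-centered (u = sd * z, z ~ N(0,1)); positive
// parameters are log-transformed with the Jacobian included, so the target
// is a proper density over the whole real space.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG_2PI = std::log(2.0 * M_PI);

// half-Cauchy(0, s) log density at x plus log-Jacobian lx = log(x)
static inline double lp_half_cauchy(double x, double lx, double s) {
  return std::log(2.0 / M_PI) - std::log(s) - std::log1p((x / s) * (x / s)) + lx;
}

// half-Normal(0, s) log density at x plus log-Jacobian lx = log(x)
static inline double lp_half_normal(double x, double lx, double s) {
  return 0.5 * std::log(2.0 / M_PI) - std::log(s) - x * x / (2.0 * s * s) + lx;
}

// [[Rcpp::export]]
Rcpp::List crp_lp_grad_cpp(const arma::vec& theta, const arma::vec& y,
                           const arma::mat& X, const arma::uvec& edu,
                           const arma::uvec& occ, int model,
                           double mu_y, double sigma_y,
                           double nu_rate, double nu_lower,
                           bool want_grad) {
  const unsigned int n = y.n_elem;
  const unsigned int p = X.n_cols;   // 13 fixed effects
  const unsigned int ne = 6, no = 9;

  unsigned int k = 0;
  const double b0 = theta(k++);
  const vec b = theta.subvec(k, k + p - 1); k += p;
  const vec ze = theta.subvec(k, k + ne - 1); k += ne;
  const vec zo = theta.subvec(k, k + no - 1); k += no;
  const double le = theta(k++), lo = theta(k++);
  const double se = std::exp(le), so = std::exp(lo);

  double ls = 0, g0 = 0, lve = 0, lvo = 0;
  vec g, zve, zvo;
  if (model == 1) {
    ls = theta(k++);
  } else {
    g0 = theta(k++);
    g = theta.subvec(k, k + p - 1); k += p;
    zve = theta.subvec(k, k + ne - 1); k += ne;
    zvo = theta.subvec(k, k + no - 1); k += no;
    lve = theta(k++); lvo = theta(k++);
  }
  const double lnu = theta(k++);
  const double num1 = std::exp(lnu);
  const double nu = nu_lower + num1;

  const vec ue = se * ze, uo = so * zo;
  vec mu = b0 + X * b + ue.elem(edu) + uo.elem(occ);

  vec sigi, eta;
  double sig = 1.0, sve = 1.0, svo = 1.0;
  if (model == 1) {
    sig = std::exp(ls);
    sigi.set_size(n);
    sigi.fill(sig);
  } else {
    sve = std::exp(lve); svo = std::exp(lvo);
    const vec vve = sve * zve, vvo = svo * zvo;
    eta = g0 + X * g + vve.elem(edu) + vvo.elem(occ);
    sigi = exp(eta);
  }

  const vec r = (y - mu) / sigi;
  const vec r2 = square(r);
  const vec denom = nu + r2;
  const vec l1p = log1p(r2 / nu);

  const double ll_const = std::lgamma((nu + 1.0) / 2.0)
    - std::lgamma(nu / 2.0) - 0.5 * std::log(nu * M_PI);
  double ll = n * ll_const - 0.5 * (nu + 1.0) * accu(l1p);
  ll -= (model == 1) ? n * ls : accu(eta);

  // priors (with transform Jacobians)
  double lp = ll;
  lp += -0.5 * LOG_2PI - std::log(sigma_y)
      - (b0 - mu_y) * (b0 - mu_y) / (2.0 * sigma_y * sigma_y);
  lp += -0.5 * p * LOG_2PI - 0.5 * dot(b, b);
  lp += -0.5 * ne * LOG_2PI - 0.5 * dot(ze, ze);
  lp += -0.5 * no * LOG_2PI - 0.5 * dot(zo, zo);
  lp += lp_half_cauchy(se, le, sigma_y);
  lp += lp_half_cauchy(so, lo, sigma_y);
  if (model == 1) {
    lp += lp_half_normal(sig, ls, sigma_y);
  } else {
    lp += -0.5 * LOG_2PI - std::log(sigma_y)
        - g0 * g0 / (2.0 * sigma_y * sigma_y);
    lp += -0.5 * p * LOG_2PI - 0.5 * dot(g, g);
    lp += -0.5 * ne * LOG_2PI - 0.5 * dot(zve, zve);
    lp += -0.5 * no * LOG_2PI - 0.5 * dot(zvo, zvo);
    lp += lp_half_normal(sve, lve, sigma_y);
    lp += lp_half_normal(svo, lvo, sigma_y);
  }
  lp += std::log(nu_rate) - nu_rate * num1 + lnu;

  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("lp") = lp);
  }

  vec grad(theta.n_elem, fill::zeros);
  const vec dmu = (nu + 1.0) * r / (sigi % denom);
  const vec rfrac = r2 / denom;

  vec gs_e(ne, fill::zeros), gs_o(no, fill::zeros);
  for (unsigned int i = 0; i < n; ++i) {
    gs_e(edu(i)) += dmu(i);
    gs_o(occ(i)) += dmu(i);
  }

  unsigned int j = 0;
  grad(j++) = accu(dmu) - (b0 - mu_y) / (sigma_y * sigma_y);
  grad.subvec(j, j + p - 1) = X.t() * dmu - b; j += p;
  grad.subvec(j, j + ne - 1) = se * gs_e - ze; j += ne;
  grad.subvec(j, j + no - 1) = so * gs_o - zo; j += no;
  grad(j++) = se * dot(ze, gs_e)
    + 1.0 - 2.0 * se * se / (sigma_y * sigma_y + se * se);
  grad(j++) = so * dot(zo, gs_o)
    + 1.0 - 2.0 * so * so / (sigma_y * sigma_y + so * so);

  if (model == 1) {
    // d/d log sigma of likelihood + half-normal prior (+ Jacobian)
    grad(j++) = accu((nu + 1.0) * rfrac) - (double) n
      + 1.0 - sig * sig / (sigma_y * sigma_y);
  } else {
    const vec deta = (nu + 1.0) * rfrac - 1.0;
    vec gs_ve(ne, fill::zeros), gs_vo(no, fill::zeros);
    for (unsigned int i = 0; i < n; ++i) {
      gs_ve(edu(i)) += deta(i);
      gs_vo(occ(i)) += deta(i);
    }
    grad(j++) = accu(deta) - g0 / (sigma_y * sigma_y);
    grad.subvec(j, j + p - 1) = X.t() * deta - g; j += p;
    grad.subvec(j, j + ne - 1) = sve * gs_ve - zve; j += ne;
    grad.subvec(j, j + no - 1) = svo * gs_vo - zvo; j += no;
    grad(j++) = sve * dot(zve, gs_ve)
      + 1.0 - sve * sve / (sigma_y * sigma_y);
    grad(j++) = svo * dot(zvo, gs_vo)
      + 1.0 - svo * svo / (sigma_y * sigma_y);
  }

  const double dll_dnu = n * (0.5 * R::digamma((nu + 1.0) / 2.0)
      - 0.5 * R::digamma(nu / 2.0) - 0.5 / nu)
    - 0.5 * accu(l1p) + (nu + 1.0) / (2.0 * nu) * accu(rfrac);
  grad(j++) = (dll_dnu - nu_rate) * num1 + 1.0;

  return Rcpp::List::create(Rcpp::Named("lp") = lp,
                            Rcpp::Named("grad") = grad);
}
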