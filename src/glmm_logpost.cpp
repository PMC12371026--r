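#include <Rcpp.h>
using namespace Rcpp;

// Log posterior and gradient of the hierarchical BEF GLMM on the
// unconstrained scale. Parameter layout in `th`:
//   beta (p) | z_realm (R) | z_site (S) | log sigma_realm | log sigma_site
//   | log shape
// family: 0 = gamma (shape phi), 1 = negative binomial (inverse shape
// omega). Non-centered random effects; half-Normal(0,1) priors on both
// scales and Gamma(0.01, 0.01) on the shape, with log-scale Jacobians.
//
// The data and index structures are frozen into a context object once per
// fit (glmmMakeContext); the sampler then evaluates glmmLpGrad with only
// the parameter vector, keeping per-leapfrog call overhead minimal.

struct GlmmCtx {
  int n, p, n_realm, n_site, family;
  std::vector<double> X;        // column-major n x p
  std::vector<double> y, lgy, offset, prior_sd, lgam_y1;
  std::vector<int> site, realm_of_site;   // 0-based
};

// [[Rcpp::export]]
SEXP glmmMakeContext(NumericMatrix X, NumericVector y, NumericVector lgy,
                     NumericVector offset, IntegerVector site,
                     IntegerVector realm_of_site, int n_realm, int n_site,
                     NumericVector prior_sd, NumericVector lgam_y1,
                     int family) {
  GlmmCtx *ctx = new GlmmCtx;
  ctx->n = X.nrow(); ctx->p = X.ncol();
  ctx->n_realm = n_realm; ctx->n_site = n_site; ctx->family = family;
  ctx->X.assign(X.begin(), X.end());
  ctx->y.assign(y.begin(), y.end());
  ctx->lgy.assign(lgy.begin(), lgy.end());
  ctx->offset.assign(offset.begin(), offset.end());
  ctx->prior_sd.assign(prior_sd.begin(), prior_sd.end());
  ctx->lgam_y1.assign(lgam_y1.begin(), lgam_y1.end());
  ctx->site.resize(ctx->n); ctx->realm_of_site.resize(n_site);
  for (int i = 0; i < ctx->n; ++i) ctx->site[i] = site[i] - 1;
  for (int s = 0; s < n_site; ++s) ctx->realm_of_site[s] = realm_of_site[s] - 1;
  XPtr<GlmmCtx> ptr(ctx, true);
  return ptr;
}

// [[Rcpp::export]]
List glmmLpGrad(SEXP ctx_ptr, NumericVector th) {
  XPtr<GlmmCtx> ctx(ctx_ptr);
  const int n = ctx->n, p = ctx->p;
  const int n_realm = ctx->n_realm, n_site = ctx->n_site;
  const int ip_lsr = p + n_realm + n_site;
  const int ip_lss = ip_lsr + 1, ip_lsh = ip_lss + 1;
  const int npar = ip_lsh + 1;
  NumericVector grad(npar);

  if (std::abs(th[ip_lsr]) > 30 || std::abs(th[ip_lss]) > 30 ||
      std::abs(th[ip_lsh]) > 30)
    return List::create(_["lp"] = R_NegInf, _["grad"] = grad);
  const double sr = std::exp(th[ip_lsr]);
  const double ss = std::exp(th[ip_lss]);
  const double sh = std::exp(th[ip_lsh]);

  std::vector<double> a_site(n_site), eta(n), ge(n);
  for (int s = 0; s < n_site; ++s)
    a_site[s] = sr * th[p + ctx->realm_of_site[s]] +
                ss * th[p + n_realm + s];
  for (int i = 0; i < n; ++i) eta[i] = ctx->offset[i] + a_site[ctx->site[i]];
  const double *Xd = ctx->X.data();
  for (int j = 0; j < p; ++j) {
    const double bj = th[j];
    const double *col = Xd + (size_t)j * n;
    for (int i = 0; i < n; ++i) eta[i] += col[i] * bj;
  }

  double ll = 0.0, dll_dlsh_acc = 0.0;
  const double lgam_sh = R::lgammafn(sh);
  const double dig_sh = R::digamma(sh);
  const double lsh = th[ip_lsh];
  for (int i = 0; i < n; ++i) {
    if (eta[i] > 250 || eta[i] < -250)
      return List::create(_["lp"] = R_NegInf, _["grad"] = grad);
    if (ctx->family == 0) {          // gamma
      const double r = ctx->y[i] * std::exp(-eta[i]);
      ll += sh * (lsh - eta[i]) + (sh - 1.0) * ctx->lgy[i] - lgam_sh -
            sh * r;
      ge[i] = sh * (r - 1.0);
      dll_dlsh_acc += lsh + 1.0 - eta[i] - dig_sh + ctx->lgy[i] - r;
    } else {                         // negative binomial
      const double mu = std::exp(eta[i]);
      const double lom = std::log(sh + mu);
      ll += R::lgammafn(ctx->y[i] + sh) - lgam_sh - ctx->lgam_y1[i] +
            sh * (lsh - lom) + ctx->y[i] * (eta[i] - lom);
      ge[i] = sh * (ctx->y[i] - mu) / (sh + mu);
      dll_dlsh_acc += R::digamma(ctx->y[i] + sh) - dig_sh + lsh + 1.0 -
                      lom - (ctx->y[i] + sh) / (sh + mu);
    }
  }

  double lp = ll;
  for (int j = 0; j < p; ++j) {
    const double *col = Xd + (size_t)j * n;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += col[i] * ge[i];
    const double psd2 = ctx->prior_sd[j] * ctx->prior_sd[j];
    lp += -0.5 * th[j] * th[j] / psd2;
    grad[j] = acc - th[j] / psd2;
  }
  std::vector<double> g_site(n_site, 0.0), g_realm(n_realm, 0.0);
  for (int i = 0; i < n; ++i) g_site[ctx->site[i]] += ge[i];
  for (int s = 0; s < n_site; ++s)
    g_realm[ctx->realm_of_site[s]] += g_site[s];
  double glsr = 0.0, glss = 0.0;
  for (int r = 0; r < n_realm; ++r) {
    const double zr = th[p + r];
    lp += -0.5 * zr * zr;
    grad[p + r] = sr * g_realm[r] - zr;
    glsr += g_realm[r] * zr;
  }
  for (int s = 0; s < n_site; ++s) {
    const double zs = th[p + n_realm + s];
    lp += -0.5 * zs * zs;
    grad[p + n_realm + s] = ss * g_site[s] - zs;
    glss += g_site[s] * zs;
  }
  // half-normal priors on the scales (+ Jacobians), Gamma(0.01,0.01) shape
  lp += -0.5 * sr * sr + th[ip_lsr] - 0.5 * ss * ss + th[ip_lss] +
        0.01 * th[ip_lsh] - 0.01 * sh;
  grad[ip_lsr] = sr * glsr - sr * sr + 1.0;
  grad[ip_lss] = ss * glss - ss * ss + 1.0;
  grad[ip_lsh] = sh * dll_dlsh_acc + 0.01 - 0.01 * sh;
  return List::create(_["lp"] = lp, _["grad"] = grad);
}
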