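// Per-variant binomial random-intercept GLMM fitted by maximum likelihood
// with per-observation adaptive Gauss-Hermite quadrature. The random
// intercept has one level per sample, so the marginal likelihood
// factorizes over observations into one-dimensional integrals; each is
// centered and scaled at the conditional mode before quadrature.

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>

using namespace Rcpp;

struct SiteData {
  const double *alt;
  const double *depth;
  const double *treat;
  int n;
  const double *ghx;
  const double *ghw;
  int nq;
  bool fix_b1;     // optimize (b0, s) with b1 held at b1_value
  double b1_value;
};

static inline double logistic(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// binomial log-likelihood kernel (no choose() constant)
static inline double binll(double a, double d, double eta) {
  // numerically stable: a*eta - d*log(1+exp(eta))
  double lse = (eta > 0) ? eta + std::log1p(std::exp(-eta))
                         : std::log1p(std::exp(eta));
  return a * eta - d * lse;
}

// marginal log-likelihood of one observation, integrating the random
// intercept: log \int Binom(a; d, logistic(eta+u)) N(u; 0, s^2) du
static double obs_marginal_ll(double a, double d, double eta, double s,
                              const double *ghx, const double *ghw, int nq) {
  if (s < 1e-6) return binll(a, d, eta);
  double s2 = s * s;
  // conditional mode by damped Newton; the integrand is log-concave so
  // g(u) = a - d p(eta+u) - u/s^2 is strictly decreasing with a unique
  // root, and any Newton failure is repaired by guarded bisection (a
  // mis-centered quadrature is not a bound and can fake a likelihood
  // spike, which the optimizer would dive into)
  double u = 0.0;
  for (int it = 0; it < 40; ++it) {
    double p = logistic(eta + u);
    double g = a - d * p - u / s2;
    double h = -d * p * (1.0 - p) - 1.0 / s2;
    double step = g / h;
    if (!std::isfinite(step)) break;
    // dampen large steps
    if (step > 5.0) step = 5.0; else if (step < -5.0) step = -5.0;
    u -= step;
    if (std::fabs(step) < 1e-10) break;
  }
  {
    double g = a - d * logistic(eta + u) - u / s2;
    if (std::fabs(g) > 1e-6 * (1.0 + d)) {
      double lo = u, hi = u;
      double width = 1.0;
      while (a - d * logistic(eta + lo) - lo / s2 < 0 && width < 1e6) {
        lo -= width; width *= 2.0;
      }
      width = 1.0;
      while (a - d * logistic(eta + hi) - hi / s2 > 0 && width < 1e6) {
        hi += width; width *= 2.0;
      }
      for (int it = 0; it < 100; ++it) {
        double mid = 0.5 * (lo + hi);
        double gm = a - d * logistic(eta + mid) - mid / s2;
        if (gm > 0) lo = mid; else hi = mid;
        if (hi - lo < 1e-12 * (1.0 + std::fabs(mid))) break;
      }
      u = 0.5 * (lo + hi);
    }
  }
  double p = logistic(eta + u);
  double curv = d * p * (1.0 - p) + 1.0 / s2;
  double sighat = 1.0 / std::sqrt(curv);
  const double sqrt2 = 1.4142135623730951;
  double scale = sqrt2 * sighat;
  double lmax = -INFINITY;
  std::vector<double> terms(nq);
  for (int k = 0; k < nq; ++k) {
    double uk = u + scale * ghx[k];
    double Hk = binll(a, d, eta + uk) - uk * uk / (2.0 * s2);
    double t = std::log(ghw[k]) + ghx[k] * ghx[k] + Hk;
    terms[k] = t;
    if (t > lmax) lmax = t;
  }
  double sum = 0.0;
  for (int k = 0; k < nq; ++k) sum += std::exp(terms[k] - lmax);
  // - log(s * sqrt(2*pi)) from the normal density, + log(scale) Jacobian
  return lmax + std::log(sum) + std::log(scale) -
         std::log(s) - 0.9189385332046727;
}

static double site_nll(int npar, double *par, void *ex) {
  SiteData *sd = static_cast<SiteData *>(ex);
  double b0 = par[0];
  double b1 = sd->fix_b1 ? sd->b1_value : par[1];
  double s = std::fabs(par[sd->fix_b1 ? 1 : 2]);
  double ll = 0.0;
  for (int i = 0; i < sd->n; ++i) {
    double eta = b0 + b1 * sd->treat[i];
    ll += obs_marginal_ll(sd->alt[i], sd->depth[i], eta, s,
                          sd->ghx, sd->ghw, sd->nq);
  }
  if (!std::isfinite(ll)) return 1e30;
  return -ll;
}

static void run_nm(SiteData *sd, std::vector<double> &par, double &fmin,
                   int &fail, int maxit) {
  int n = (int)par.size();
  std::vector<double> xout(n);
  int fncount = 0;
  nmmin(n, par.data(), xout.data(), &fmin, site_nll, &fail, -INFINITY, 1e-10,
        sd, 1.0, 0.5, 2.0, 0, &fncount, maxit);
  par = xout;
}

// central-difference Hessian of the nll restricted to indices `which`
static void num_hessian(SiteData *sd, std::vector<double> par,
                        const std::vector<int> &which, double *H) {
  // steps sized well above the quadrature/optimizer noise floor: with
  // h ~ 5e-3 the truncation error is ~1e-5 relative while the numerator
  // differences stay orders of magnitude above the ~1e-10 nll noise
  int m = (int)which.size();
  for (int i = 0; i < m; ++i) {
    for (int j = i; j < m; ++j) {
      double hi = 5e-3 * (1.0 + std::fabs(par[which[i]]));
      double hj = 5e-3 * (1.0 + std::fabs(par[which[j]]));
      std::vector<double> p = par;
      double f = 0.0;
      if (i == j) {
        p[which[i]] = par[which[i]] + hi;
        double fp = site_nll((int)p.size(), p.data(), sd);
        p[which[i]] = par[which[i]] - hi;
        double fm = site_nll((int)p.size(), p.data(), sd);
        p[which[i]] = par[which[i]];
        double f0 = site_nll((int)p.size(), p.data(), sd);
        f = (fp - 2.0 * f0 + fm) / (hi * hi);
      } else {
        p[which[i]] = par[which[i]] + hi; p[which[j]] = par[which[j]] + hj;
        double fpp = site_nll((int)p.size(), p.data(), sd);
        p[which[j]] = par[which[j]] - hj;
        double fpm = site_nll((int)p.size(), p.data(), sd);
        p[which[i]] = par[which[i]] - hi; p[which[j]] = par[which[j]] + hj;
        double fmp = site_nll((int)p.size(), p.data(), sd);
        p[which[j]] = par[which[j]] - hj;
        double fmm = site_nll((int)p.size(), p.data(), sd);
        f = (fpp - fpm - fmp + fmm) / (4.0 * hi * hj);
      }
      H[i * m + j] = f;
      H[j * m + i] = f;
    }
  }
}

// standard error of b1 from the observed information. The 3x3 observed
// information can be ill-conditioned on flat ridges, so the result is
// sanity-checked against the fixed-variance information (profiling over
// the variance can only widen the interval) and, when implausible,
// recomputed from profile-likelihood curvature via constrained refits.
static double se_fixed_s(SiteData *sd, std::vector<double> par) {
  std::vector<int> which = {0, 1};
  double H[4];
  num_hessian(sd, par, which, H);
  double det = H[0] * H[3] - H[1] * H[2];
  if (det <= 0) return NA_REAL;
  double v = H[0] / det;
  return v > 0 ? std::sqrt(v) : NA_REAL;
}

static double se_profile(SiteData *sd, const std::vector<double> &par,
                         double fmin, double h, int maxit) {
  SiteData sp = *sd;
  sp.fix_b1 = true;
  double pl[2];
  for (int k = 0; k < 2; ++k) {
    sp.b1_value = par[1] + (k == 0 ? h : -h);
    std::vector<double> q = {par[0], par[2]};
    double f;
    int fail;
    run_nm(&sp, q, f, fail, maxit);
    pl[k] = f;
  }
  double curv = (pl[0] + pl[1] - 2.0 * fmin) / (h * h);
  if (!(curv > 0) || !std::isfinite(curv)) return NA_REAL;
  return 1.0 / std::sqrt(curv);
}

static double se_beta1(SiteData *sd, std::vector<double> par, double fmin,
                       int maxit) {
  double s = std::fabs(par[2]);
  if (s < 1e-4) {
    par[2] = 0.0;
    return se_fixed_s(sd, par);
  }
  double se2 = se_fixed_s(sd, par);
  std::vector<int> which = {0, 1, 2};
  double H[9];
  num_hessian(sd, par, which, H);
  double a = H[0], b = H[1], c = H[2], d = H[3], e = H[4], f = H[5],
         g = H[6], hh = H[7], i = H[8];
  double det = a * (e * i - f * hh) - b * (d * i - f * g) +
               c * (d * hh - e * g);
  if (det != 0 && std::isfinite(det)) {
    double v = (a * i - c * g) / det;
    // with the variance profiled out, the b1 variance cannot shrink below
    // its fixed-variance counterpart
    if (v > 0 && std::isfinite(v) &&
        (!std::isfinite(se2) || std::sqrt(v) >= 0.95 * se2))
      return std::sqrt(v);
  }
  double h0 = std::isfinite(se2) ? std::max(0.5 * se2, 1e-2) : 0.25;
  double sep = se_profile(sd, par, fmin, h0, maxit);
  if (std::isfinite(sep) && (!std::isfinite(se2) || sep >= 0.95 * se2))
    return sep;
  return std::isfinite(se2) ? se2 : NA_REAL;
}

static inline double clamped_logit(double num, double den) {
  double lo = 0.5 / std::max(den, 1.0);
  double p = num / std::max(den, 1.0);
  if (p < lo) p = lo;
  if (p > 1.0 - lo) p = 1.0 - lo;
  return std::log(p / (1.0 - p));
}

// [[Rcpp::export(name = ".fit_glmm_batch")]]
List fit_glmm_batch(NumericMatrix alt, NumericMatrix depth,
                    NumericMatrix treat, NumericVector ghx,
                    NumericVector ghw, int maxit = 500) {
  int ns = alt.nrow();      // sites
  int n = alt.ncol();       // observations (samples)
  int nl = treat.nrow();    // labelings
  if (depth.nrow() != ns || depth.ncol() != n || treat.ncol() != n)
    stop("dimension mismatch");

  NumericMatrix b0(ns, nl), b1(ns, nl), sig(ns, nl), se1(ns, nl),
      ll(ns, nl);
  IntegerMatrix conv(ns, nl), sep(ns, nl);
  NumericVector ll0(ns);

  std::vector<double> a(n), d(n), t(n);
  for (int isite = 0; isite < ns; ++isite) {
    for (int i = 0; i < n; ++i) {
      a[i] = alt(isite, i);
      d[i] = depth(isite, i);
    }
    SiteData sd;
    sd.alt = a.data(); sd.depth = d.data(); sd.treat = t.data();
    sd.n = n; sd.ghx = ghx.begin(); sd.ghw = ghw.begin();
    sd.nq = ghx.size();

    // null model (shared across labelings)
    sd.fix_b1 = true;
    sd.b1_value = 0.0;
    double atot = 0, dtot = 0;
    for (int i = 0; i < n; ++i) { atot += a[i]; dtot += d[i]; }
    std::vector<double> par0 = {clamped_logit(atot, dtot), 0.3};
    double f0; int fail0;
    run_nm(&sd, par0, f0, fail0, maxit);
    ll0[isite] = -f0;

    sd.fix_b1 = false;
    for (int il = 0; il < nl; ++il) {
      double a1 = 0, d1 = 0, a0 = 0, d0 = 0;
      for (int i = 0; i < n; ++i) {
        t[i] = treat(il, i);
        if (t[i] > 0.5) { a1 += a[i]; d1 += d[i]; }
        else { a0 += a[i]; d0 += d[i]; }
      }
      bool separated = (a1 == 0 || a1 == d1 || a0 == 0 || a0 == d0) &&
                       !(a1 == 0 && a0 == 0) && !(a1 == d1 && a0 == d0);
      double l0 = clamped_logit(a0, d0);
      double l1 = clamped_logit(a1, d1);
      std::vector<double> par = {l0, l1 - l0, 0.3};
      double fmin; int fail;
      run_nm(&sd, par, fmin, fail, maxit);
      // restart from the first optimum: a single Nelder-Mead pass can
      // collapse the variance prematurely, which turns a moderate test
      // statistic into an astronomical one
      double fmin2; int fail2;
      std::vector<double> par2 = par;
      run_nm(&sd, par2, fmin2, fail2, maxit);
      if (fmin2 < fmin) { par = par2; fmin = fmin2; fail = fail2; }
      b0(isite, il) = par[0];
      b1(isite, il) = par[1];
      sig(isite, il) = std::fabs(par[2]);
      ll(isite, il) = -fmin;
      conv(isite, il) = (fail == 0) ? 1 : 0;
      sep(isite, il) = separated ? 1 : 0;
      se1(isite, il) = se_beta1(&sd, par, fmin, maxit);
    }
  }
  return List::create(_["beta0"] = b0, _["beta1"] = b1, _["sigma"] = sig,
                      _["se1"] = se1, _["loglik"] = ll,
                      _["loglik_null"] = ll0, _["converged"] = conv,
                      _["separated"] = sep);
}
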