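// Subject-level Laplace machinery for the two-compartment NLME model.
//
// Each subject is a list: y (observed conc), tsd (nobs x ndose matrix of
// time-since-dose-start, h), tinf (per-dose infusion duration, h), rate
// (per-dose infusion rate, mg/h). Random effects eta act multiplicatively
// (exp link) on CL, Vc, Vp in that order; Q carries none. The residual
// model is Y = F + F^power * eps, eps ~ N(0, sigma^2), giving conditional
// variance v = sigma^2 * F^(2*power) (interaction: v evaluated at the
// conditional prediction).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Central concentration at the subject's observation times for one
// parameter set, by superposition over all administered infusions.
static void conc_subject(double cl, double vc, double vp, double q,
                         const NumericMatrix &tsd,
                         const NumericVector &tinf,
                         const NumericVector &rate,
                         std::vector<double> &out) {
  const double k10 = cl / vc, k12 = q / vc, k21 = q / vp;
  const double s = k10 + k12 + k21;
  double disc2 = s * s - 4.0 * k10 * k21;
  const double floor2 = (1e-9 * s) * (1e-9 * s);
  const double disc = std::sqrt(disc2 > floor2 ? disc2 : floor2);
  const double alpha = (s + disc) / 2.0, beta = (s - disc) / 2.0;
  const double A = (alpha - k21) / (alpha - beta);
  const double B = (k21 - beta) / (alpha - beta);
  const double ca = A / alpha, cb = B / beta;
  const int nobs = tsd.nrow(), ndose = tsd.ncol();
  out.assign(nobs, 0.0);
  for (int j = 0; j < ndose; ++j) {
    const double ti = tinf[j], rv = rate[j] / vc;
    const double eai = 1.0 - std::exp(-alpha * ti);
    const double ebi = 1.0 - std::exp(-beta * ti);
    for (int i = 0; i < nobs; ++i) {
      const double t = tsd(i, j);
      if (t <= 0.0) continue;
      if (t <= ti) {
        out[i] += rv * (ca * (1.0 - std::exp(-alpha * t)) +
                        cb * (1.0 - std::exp(-beta * t)));
      } else {
        out[i] += rv * (ca * eai * std::exp(-alpha * (t - ti)) +
                        cb * ebi * std::exp(-beta * (t - ti)));
      }
    }
  }
}

struct SubjectData {
  NumericVector y, tinf, rate;
  NumericMatrix tsd;
  double tvcl, tvvc, tvvp, q;
  // indices (0,1,2 = CL,Vc,Vp) of etas with omega > 0
  std::vector<int> free_idx;
  std::vector<double> om2; // omega^2 for free etas
  double sigma2, power;
};

// negative log joint density g(eta) = -log p(y|eta) - log p(eta),
// including all 2*pi constants (they cancel consistently in the OFV).
static double neg_log_joint(const SubjectData &d,
                            const std::vector<double> &eta_free,
                            std::vector<double> &work) {
  double e[3] = {0.0, 0.0, 0.0};
  for (size_t k = 0; k < d.free_idx.size(); ++k) e[d.free_idx[k]] = eta_free[k];
  const double cl = d.tvcl * std::exp(e[0]);
  const double vc = d.tvvc * std::exp(e[1]);
  const double vp = d.tvvp * std::exp(e[2]);
  conc_subject(cl, vc, vp, d.q, d.tsd, d.tinf, d.rate, work);
  const double LOG2PI = 1.8378770664093453;
  double g = 0.0;
  for (int i = 0; i < d.y.size(); ++i) {
    double f = work[i] > 1e-12 ? work[i] : 1e-12;
    double v = d.sigma2 * std::pow(f, 2.0 * d.power);
    if (v < 1e-300) v = 1e-300;
    const double r = d.y[i] - f;
    g += 0.5 * (LOG2PI + std::log(v) + r * r / v);
  }
  for (size_t k = 0; k < d.free_idx.size(); ++k) {
    g += 0.5 * (LOG2PI + std::log(d.om2[k]) +
                eta_free[k] * eta_free[k] / d.om2[k]);
  }
  return g;
}

// Cholesky of a small (d<=3) symmetric matrix; returns false if not PD.
static bool chol_small(int n, const double *a, double *l) {
  for (int i = 0; i < n * n; ++i) l[i] = 0.0;
  for (int j = 0; j < n; ++j) {
    double s = a[j * n + j];
    for (int k = 0; k < j; ++k) s -= l[j * n + k] * l[j * n + k];
    if (s <= 0.0) return false;
    l[j * n + j] = std::sqrt(s);
    for (int i = j + 1; i < n; ++i) {
      double t = a[i * n + j];
      for (int k = 0; k < j; ++k) t -= l[i * n + k] * l[j * n + k];
      l[i * n + j] = t / l[j * n + j];
    }
  }
  return true;
}

static void chol_solve(int n, const double *l, const double *b, double *x) {
  // solve L L' x = b
  double y[3];
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= l[i * n + k] * y[k];
    y[i] = s / l[i * n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < n; ++k) s -= l[k * n + i] * x[k];
    x[i] = s / l[i * n + i];
  }
}

static void fd_grad_hess(const SubjectData &d, const std::vector<double> &eta,
                         double g0, std::vector<double> &work,
                         double *grad, double *hess) {
  const int n = (int)eta.size();
  const double h = 1e-4;
  std::vector<double> e(eta);
  double gp[3], gm[3];
  for (int i = 0; i < n; ++i) {
    e[i] = eta[i] + h; gp[i] = neg_log_joint(d, e, work);
    e[i] = eta[i] - h; gm[i] = neg_log_joint(d, e, work);
    e[i] = eta[i];
    grad[i] = (gp[i] - gm[i]) / (2.0 * h);
    hess[i * n + i] = (gp[i] - 2.0 * g0 + gm[i]) / (h * h);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      e[i] = eta[i] + h; e[j] = eta[j] + h;
      double gpp = neg_log_joint(d, e, work);
      e[j] = eta[j] - h;
      double gpm = neg_log_joint(d, e, work);
      e[i] = eta[i] - h; e[j] = eta[j] + h;
      double gmp = neg_log_joint(d, e, work);
      e[j] = eta[j] - h;
      double gmm = neg_log_joint(d, e, work);
      e[i] = eta[i]; e[j] = eta[j];
      hess[i * n + j] = hess[j * n + i] = (gpp - gpm - gmp + gmm) / (4.0 * h * h);
    }
  }
}

// Damped Newton minimisation of g(eta) from eta = 0.
static bool inner_newton(const SubjectData &d, std::vector<double> &eta,
                         double &gmin, std::vector<double> &work) {
  const int n = (int)eta.size();
  std::fill(eta.begin(), eta.end(), 0.0);
  gmin = neg_log_joint(d, eta, work);
  if (n == 0) return true;
  double grad[3], hess[9], l[9], step[3], hridge[9];
  for (int iter = 0; iter < 100; ++iter) {
    fd_grad_hess(d, eta, gmin, work, grad, hess);
    double gnorm = 0.0;
    for (int i = 0; i < n; ++i) gnorm = std::max(gnorm, std::fabs(grad[i]));
    if (gnorm < 1e-7) return true;
    double lambda = 0.0;
    bool moved = false;
    for (int tries = 0; tries < 12 && !moved; ++tries) {
      for (int i = 0; i < n * n; ++i) hridge[i] = hess[i];
      for (int i = 0; i < n; ++i) hridge[i * n + i] += lambda;
      if (chol_small(n, hridge, l)) {
        double nb[3];
        for (int i = 0; i < n; ++i) nb[i] = -grad[i];
        chol_solve(n, l, nb, step);
        std::vector<double> cand(eta);
        for (int i = 0; i < n; ++i) cand[i] = eta[i] + step[i];
        double gc = neg_log_joint(d, cand, work);
        if (gc < gmin) {
          eta = cand; gmin = gc; moved = true;
        }
      }
      if (!moved) lambda = (lambda == 0.0) ? 1e-3 : lambda * 10.0;
    }
    if (!moved) return gnorm < 1e-3; // stuck; accept if gradient small-ish
  }
  return false;
}

// [[Rcpp::export(name = ".nlme_ofv_cpp")]]
List nlme_ofv_cpp(List subjects, NumericVector tvcl,
                  double vc, double q, double vp,
                  NumericVector omega, double sigma, double power,
                  bool detail = false) {
  const int ns = subjects.size();
  const double LOG2PI = 1.8378770664093453;
  std::vector<int> free_idx;
  std::vector<double> om2;
  for (int k = 0; k < 3; ++k) {
    if (omega[k] > 0.0) { free_idx.push_back(k); om2.push_back(omega[k] * omega[k]); }
  }
  const int d = (int)free_idx.size();
  double total = 0.0;
  NumericVector ofv_i(ns);
  NumericMatrix eta_hat(ns, 3);
  LogicalVector conv(ns);
  List det(detail ? ns : 0);
  std::vector<double> work;
  int nobs_total = 0;
  for (int s = 0; s < ns; ++s) {
    List sub = subjects[s];
    SubjectData dat;
    dat.y = as<NumericVector>(sub["y"]);
    dat.tsd = as<NumericMatrix>(sub["tsd"]);
    dat.tinf = as<NumericVector>(sub["tinf"]);
    dat.rate = as<NumericVector>(sub["rate"]);
    dat.tvcl = tvcl[s]; dat.tvvc = vc; dat.tvvp = vp; dat.q = q;
    dat.free_idx = free_idx; dat.om2 = om2;
    dat.sigma2 = sigma * sigma; dat.power = power;
    const int nobs = dat.y.size();
    nobs_total += nobs;
    std::vector<double> eta(d, 0.0);
    double gmin;
    conv[s] = inner_newton(dat, eta, gmin, work);
    double contrib = 2.0 * gmin - nobs * LOG2PI; // drop n*log(2pi), NONMEM style
    if (d > 0) {
      double grad[3], hess[9], l[9];
      fd_grad_hess(dat, eta, gmin, work, grad, hess);
      double ridge = 0.0;
      double hridge[9];
      bool pd = false;
      for (int tries = 0; tries < 10 && !pd; ++tries) {
        for (int i = 0; i < d * d; ++i) hridge[i] = hess[i];
        for (int i = 0; i < d; ++i) hridge[i * d + i] += ridge;
        pd = chol_small(d, hridge, l);
        if (!pd) { ridge = (ridge == 0.0) ? 1e-6 : ridge * 100.0; conv[s] = false; }
      }
      double logdet_h = 0.0;
      for (int i = 0; i < d; ++i) logdet_h += 2.0 * std::log(l[i * d + i]);
      contrib += logdet_h - d * LOG2PI;
    }
    ofv_i[s] = contrib;
    total += contrib;
    for (int k = 0; k < d; ++k) eta_hat(s, free_idx[k]) = eta[k];
    if (detail) {
      // conditional prediction, variance and dF/deta at the mode
      double e[3] = {eta_hat(s, 0), eta_hat(s, 1), eta_hat(s, 2)};
      std::vector<double> f0;
      conc_subject(dat.tvcl * std::exp(e[0]), vc * std::exp(e[1]),
                   vp * std::exp(e[2]), q, dat.tsd, dat.tinf, dat.rate, f0);
      NumericMatrix G(nobs, 3);
      const double h = 1e-5;
      for (int k = 0; k < 3; ++k) {
        double ep[3] = {e[0], e[1], e[2]}, em[3] = {e[0], e[1], e[2]};
        ep[k] += h; em[k] -= h;
        std::vector<double> fp, fm;
        conc_subject(dat.tvcl * std::exp(ep[0]), vc * std::exp(ep[1]),
                     vp * std::exp(ep[2]), q, dat.tsd, dat.tinf, dat.rate, fp);
        conc_subject(dat.tvcl * std::exp(em[0]), vc * std::exp(em[1]),
                     vp * std::exp(em[2]), q, dat.tsd, dat.tinf, dat.rate, fm);
        for (int i = 0; i < nobs; ++i) G(i, k) = (fp[i] - fm[i]) / (2.0 * h);
      }
      NumericVector fhat(nobs), vhat(nobs);
      for (int i = 0; i < nobs; ++i) {
        double f = f0[i] > 1e-12 ? f0[i] : 1e-12;
        fhat[i] = f0[i];
        vhat[i] = dat.sigma2 * std::pow(f, 2.0 * power);
      }
      det[s] = List::create(_["f_hat"] = fhat, _["v_hat"] = vhat, _["G"] = G);
    }
  }
  List out = List::create(_["ofv"] = total, _["ofv_subject"] = ofv_i,
                          _["eta_hat"] = eta_hat, _["converged"] = conv,
                          _["n_obs"] = nobs_total);
  if (detail) out["detail"] = det;
  return out;
}

// Exposed for tests: central concentration at observation times for one
// subject design and explicit individual parameters.
// [[Rcpp::export(name = ".conc_design_cpp")]]
NumericVector conc_design_cpp(double cl, double vc, double vp, double q,
                              NumericMatrix tsd, NumericVector tinf,
                              NumericVector rate) {
  std::vector<double> out;
  conc_subject(cl, vc, vp, q, tsd, tinf, rate, out);
  return NumericVector(out.begin(), out.end());
}
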