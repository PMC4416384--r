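// Laplace (FOCE-style) marginal likelihood machinery for the HTB
// population PK-PD model.  The per-subject inner optimisation over the
// random effects eta is the hot loop of population estimation, so it
// lives here; the outer optimisation over the population parameters is
// plain nlminb on the R side.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// One-compartment, first-order input, closed-form superposition over
// doses.  kf -> ke degeneracy switches to the D/V * ke * t * exp(-ke t)
// limit when |kf - ke| < 1e-8 * ke.
static double conc_point(double t, const arma::vec& dose_t,
                         const arma::vec& dose_a,
                         double cl, double v, double kf) {
  double ke = cl / v;
  double c = 0.0;
  for (arma::uword i = 0; i < dose_t.n_elem; ++i) {
    if (dose_t[i] > t) break;  // dose times sorted ascending
    double dt = t - dose_t[i];
    double term;
    if (std::fabs(kf - ke) <= 1e-8 * ke)
      term = ke * dt * std::exp(-ke * dt);
    else
      term = kf / (kf - ke) * (std::exp(-ke * dt) - std::exp(-kf * dt));
    c += dose_a[i] / v * term;
  }
  return c > 0.0 ? c : 0.0;
}

// [[Rcpp::export]]
arma::vec conc_profile_cpp(const arma::vec& times, const arma::vec& dose_t,
                           const arma::vec& dose_a, double cl, double v,
                           double kf) {
  if (cl <= 0.0 || v <= 0.0 || kf <= 0.0)
    stop("cl, v and kf must be positive");
  arma::vec out(times.n_elem);
  for (arma::uword i = 0; i < times.n_elem; ++i)
    out[i] = conc_point(times[i], dose_t, dose_a, cl, v, kf);
  return out;
}

typedef std::function<double(const arma::vec&)> ObjFn;

static arma::vec num_grad(const ObjFn& f, const arma::vec& x, double h) {
  arma::vec g(x.n_elem);
  arma::vec xp = x;
  for (arma::uword j = 0; j < x.n_elem; ++j) {
    double hj = h * (1.0 + std::fabs(x[j]));
    xp[j] = x[j] + hj; double fp = f(xp);
    xp[j] = x[j] - hj; double fm = f(xp);
    xp[j] = x[j];
    g[j] = (fp - fm) / (2.0 * hj);
  }
  return g;
}

static arma::mat num_hess(const ObjFn& f, const arma::vec& x, double h) {
  arma::uword k = x.n_elem;
  arma::mat H(k, k);
  double f0 = f(x);
  arma::vec hv(k);
  for (arma::uword j = 0; j < k; ++j) hv[j] = h * (1.0 + std::fabs(x[j]));
  arma::vec xp = x;
  for (arma::uword j = 0; j < k; ++j) {
    xp[j] = x[j] + hv[j]; double fp = f(xp);
    xp[j] = x[j] - hv[j]; double fm = f(xp);
    xp[j] = x[j];
    H(j, j) = (fp - 2.0 * f0 + fm) / (hv[j] * hv[j]);
  }
  for (arma::uword j = 0; j < k; ++j) {
    for (arma::uword l = j + 1; l < k; ++l) {
      xp[j] = x[j] + hv[j]; xp[l] = x[l] + hv[l]; double fpp = f(xp);
      xp[l] = x[l] - hv[l];                        double fpm = f(xp);
      xp[j] = x[j] - hv[j]; xp[l] = x[l] + hv[l];  double fmp = f(xp);
      xp[l] = x[l] - hv[l];                        double fmm = f(xp);
      xp[j] = x[j]; xp[l] = x[l];
      H(j, l) = H(l, j) = (fpp - fpm - fmp + fmm) / (4.0 * hv[j] * hv[l]);
    }
  }
  return H;
}

// Damped Newton minimisation of g over eta (dimension <= 3); finite
// difference derivatives.  Returns minimised value; eta is updated in
// place; ok reports gradient-norm convergence.
static double inner_newton(const ObjFn& g, arma::vec& eta, bool& ok,
                           int max_iter = 60) {
  const double gh = 1e-5, hh = 1e-4;
  double lambda = 0.0;
  double g0 = g(eta);
  ok = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec grad = num_grad(g, eta, gh);
    double tol = 1e-8 * (1.0 + std::fabs(g0));
    if (arma::norm(grad, "inf") < tol) { ok = true; break; }
    arma::mat H = num_hess(g, eta, hh);
    bool stepped = false;
    for (int attempt = 0; attempt < 12; ++attempt) {
      arma::mat Hd = H;
      Hd.diag() += lambda;
      arma::vec step;
      bool solved = arma::solve(step, Hd, -grad, arma::solve_opts::no_approx);
      if (solved && arma::dot(step, grad) < 0.0) {
        // cap absurd steps
        double sn = arma::norm(step, "inf");
        if (sn > 5.0) step *= 5.0 / sn;
        arma::vec etan = eta + step;
        double gn = g(etan);
        if (std::isfinite(gn) && gn <= g0 - 1e-13 * (1.0 + std::fabs(g0))) {
          eta = etan; g0 = gn;
          lambda = (lambda > 1e-10) ? lambda * 0.25 : 0.0;
          stepped = true;
          break;
        }
      }
      lambda = (lambda < 1e-6) ? 1e-4 : lambda * 10.0;
      if (lambda > 1e8) break;
    }
    if (!stepped) {  // gradient fallback with backtracking
      double s = 1e-2;
      bool moved = false;
      for (int bt = 0; bt < 20; ++bt) {
        arma::vec etan = eta - s * grad;
        double gn = g(etan);
        if (std::isfinite(gn) && gn < g0) { eta = etan; g0 = gn; moved = true; break; }
        s *= 0.5;
      }
      if (!moved) break;
    }
  }
  // final gradient check
  arma::vec grad = num_grad(g, eta, gh);
  if (arma::norm(grad, "inf") < 1e-5 * (1.0 + std::fabs(g0))) ok = true;
  return g0;
}

// log det of the (regularised) Hessian of g at eta.
static double logdet_hess(const ObjFn& g, const arma::vec& eta, bool& pd) {
  arma::mat H = num_hess(g, eta, 1e-4);
  H = 0.5 * (H + H.t());
  double jitter = 0.0;
  for (int t = 0; t < 8; ++t) {
    arma::mat Hj = H;
    Hj.diag() += jitter;
    arma::mat R;
    if (arma::chol(R, Hj)) {
      pd = (t == 0);
      return 2.0 * arma::sum(arma::log(R.diag()));
    }
    jitter = (jitter == 0.0) ? 1e-8 : jitter * 100.0;
  }
  pd = false;
  return R_PosInf;  // degenerate; caller flags subject
}

struct PkSubject {
  arma::vec obs_t, obs_y, dose_t, dose_a;
  double cl_typ, v_typ, kf_typ;
};

// Negative joint log density g(eta) = -log p(y | eta) - log phi(eta; 0, Omega)
// over the ACTIVE eta dimensions (omega^2 > 1e-12); inactive dims pinned
// at zero with no prior term.  Residual variance is evaluated at the
// conditional prediction (FOCE "with interaction" analog).
static double pk_g(const arma::vec& eta_act, const PkSubject& s,
                   const arma::uvec& act, const arma::vec& om2,
                   double sp2, double sa2) {
  double e[3] = {0.0, 0.0, 0.0};
  for (arma::uword j = 0; j < act.n_elem; ++j) e[act[j]] = eta_act[j];
  if (std::fabs(e[0]) > 40 || std::fabs(e[1]) > 40 || std::fabs(e[2]) > 40)
    return 1e30;
  double cl = s.cl_typ * std::exp(e[0]);
  double v  = s.v_typ  * std::exp(e[1]);
  double kf = s.kf_typ * std::exp(e[2]);
  double nll = 0.0;
  for (arma::uword i = 0; i < s.obs_t.n_elem; ++i) {
    double f = conc_point(s.obs_t[i], s.dose_t, s.dose_a, cl, v, kf);
    double var = sp2 * f * f + sa2;
    if (!(var > 0.0)) return 1e30;
    double r = s.obs_y[i] - f;
    nll += 0.5 * (std::log(TWO_PI * var) + r * r / var);
  }
  for (arma::uword j = 0; j < act.n_elem; ++j) {
    double o2 = om2[act[j]];
    nll += 0.5 * (std::log(TWO_PI * o2) + eta_act[j] * eta_act[j] / o2);
  }
  return nll;
}

static void gh_rule(int n, arma::vec& nodes, arma::vec& weights);

// -2 log marginal likelihood for the PK model, all subjects.  The
// per-subject integral over the active random effects uses the Laplace
// approximation (n_nodes = 1) or adaptive Gauss-Hermite quadrature with
// a tensor-product rule centred at the conditional mode and scaled by
// the inverse Cholesky factor of the Hessian (n_nodes > 1).
// Flattened per-subject data with 0-based pointer arrays (length n+1).
// [[Rcpp::export]]
List laplace_pk_ofv_cpp(const arma::vec& obs_t, const arma::vec& obs_y,
                        const arma::ivec& obs_ptr,
                        const arma::vec& dose_t, const arma::vec& dose_a,
                        const arma::ivec& dose_ptr,
                        const arma::vec& cl_typ, const arma::vec& v_typ,
                        const arma::vec& kf_typ,
                        const arma::vec& om2, double sp2, double sa2,
                        const arma::mat& eta_init, int n_nodes = 1) {
  int n = cl_typ.n_elem;
  arma::uvec act = arma::find(om2 > 1e-12);
  int k = act.n_elem;
  arma::mat eta_out(n, 3, arma::fill::zeros);
  arma::vec contrib(n);
  LogicalVector okv(n);
  arma::vec nodes, weights;
  if (k > 0 && n_nodes > 1) gh_rule(n_nodes, nodes, weights);
  int n_pts = 1;
  for (int j = 0; j < k; ++j) n_pts *= (n_nodes > 1 ? n_nodes : 1);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    PkSubject s;
    s.obs_t = obs_t.subvec(obs_ptr[i], obs_ptr[i + 1] - 1);
    s.obs_y = obs_y.subvec(obs_ptr[i], obs_ptr[i + 1] - 1);
    s.dose_t = dose_t.subvec(dose_ptr[i], dose_ptr[i + 1] - 1);
    s.dose_a = dose_a.subvec(dose_ptr[i], dose_ptr[i + 1] - 1);
    s.cl_typ = cl_typ[i]; s.v_typ = v_typ[i]; s.kf_typ = kf_typ[i];
    ObjFn g = [&](const arma::vec& e) { return pk_g(e, s, act, om2, sp2, sa2); };
    double ci;
    bool ok = true;
    if (k == 0) {
      arma::vec e0;
      ci = 2.0 * g(e0);
    } else {
      arma::vec eta(k);
      for (int j = 0; j < k; ++j) eta[j] = eta_init(i, act[j]);
      double gmin = inner_newton(g, eta, ok);
      if (!ok) {  // retry from zero, then perturbed
        arma::vec eta2(k, arma::fill::zeros);
        bool ok2;
        double g2 = inner_newton(g, eta2, ok2);
        if (g2 < gmin) { gmin = g2; eta = eta2; ok = ok2; }
      }
      arma::mat H = num_hess(g, eta, 1e-4);
      H = 0.5 * (H + H.t());
      arma::mat R;
      double jitter = 0.0;
      bool chol_ok = false;
      for (int t = 0; t < 8 && !chol_ok; ++t) {
        arma::mat Hj = H;
        Hj.diag() += jitter;
        chol_ok = arma::chol(R, Hj);  // H = R' R, upper triangular
        jitter = (jitter == 0.0) ? 1e-8 : jitter * 100.0;
      }
      if (!chol_ok) {  // degenerate curvature: fall back to the prior
        ok = false;
        R.eye(k, k);
        for (int j = 0; j < k; ++j) R(j, j) = 1.0 / std::sqrt(om2[act[j]]);
      }
      double logdetR = 0.0;
      for (int j = 0; j < k; ++j) logdetR += std::log(R(j, j));
      if (n_nodes <= 1) {
        ci = 2.0 * gmin + 2.0 * logdetR - k * std::log(TWO_PI);
      } else {
        // eta = eta_hat + sqrt(2) R^{-1} z, tensor-product GH rule
        arma::mat Rinv = arma::inv(arma::trimatu(R));
        arma::ivec idx(k, arma::fill::zeros);
        double lse = -arma::datum::inf;
        arma::vec terms(n_pts);
        for (int p = 0; p < n_pts; ++p) {
          arma::vec z(k);
          double lw = 0.0;
          for (int j = 0; j < k; ++j) {
            z[j] = nodes[idx[j]];
            lw += std::log(weights[idx[j]]) + z[j] * z[j];
          }
          arma::vec e1 = eta + std::sqrt(2.0) * (Rinv * z);
          terms[p] = lw - g(e1);
          if (terms[p] > lse) lse = terms[p];
          for (int j = 0; j < k; ++j) {  // odometer increment
            if (++idx[j] < n_nodes) break;
            idx[j] = 0;
          }
        }
        double acc = 0.0;
        for (int p = 0; p < n_pts; ++p) acc += std::exp(terms[p] - lse);
        double logL = 0.5 * k * std::log(2.0) - logdetR + lse +
          std::log(acc);
        ci = -2.0 * logL;
      }
      for (int j = 0; j < k; ++j) eta_out(i, act[j]) = eta[j];
    }
    contrib[i] = ci;
    okv[i] = ok;
    total += ci;
  }
  return List::create(_["ofv"] = total, _["contrib"] = contrib,
                      _["eta"] = eta_out, _["ok"] = okv);
}

// Stable Bernoulli log-likelihood for the Hill probability model on the
// logit scale: z = gamma * (log c - log ec50), p = plogis(z); c = 0 gives
// p = 0 under a 1e-10 clamp.
static double bern_ll(int dv, double conc, double log_ec50, double gamma) {
  if (conc <= 0.0) return dv == 1 ? std::log(1e-10) : 0.0;
  double z = gamma * (std::log(conc) - log_ec50);
  // log p = -softplus(-z); log(1-p) = -softplus(z)
  double sp_neg = (-z > 30.0) ? -z : std::log1p(std::exp(-z));
  double sp_pos = (z > 30.0) ? z : std::log1p(std::exp(z));
  double lp = dv == 1 ? -sp_neg : -sp_pos;
  double lcl = std::log(1e-10);
  return lp < lcl ? lcl : lp;
}

struct PdSubject {
  arma::vec conc;
  arma::ivec dv;
};

static double pd_g(const arma::vec& eta_act, const PdSubject& s,
                   bool active, double om2, double log_ec50, double gamma) {
  double e = active ? eta_act[0] : 0.0;
  if (std::fabs(e) > 40) return 1e30;
  double nll = 0.0;
  for (arma::uword i = 0; i < s.conc.n_elem; ++i)
    nll -= bern_ll(s.dv[i], s.conc[i], log_ec50 + e, gamma);
  if (active)
    nll += 0.5 * (std::log(TWO_PI * om2) + e * e / om2);
  return nll;
}

// Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
static void gh_rule(int n, arma::vec& nodes, arma::vec& weights) {
  arma::mat J(n, n, arma::fill::zeros);
  for (int i = 1; i < n; ++i) {
    double b = std::sqrt(i / 2.0);
    J(i - 1, i) = b;
    J(i, i - 1) = b;
  }
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, J);
  nodes = ev;
  weights.set_size(n);
  for (int i = 0; i < n; ++i)
    weights[i] = V(0, i) * V(0, i) * std::sqrt(M_PI);
}

// Adaptive Gauss-Hermite -2 log marginal likelihood for the binary PD
// model with one lognormal random effect on EC50.  The rule is centred
// and scaled at the conditional mode; n_nodes = 1 reduces exactly to the
// Laplace approximation (sqrt(2) s sqrt(pi) = sqrt(2 pi) s).
// [[Rcpp::export]]
List laplace_pd_ofv_cpp(const arma::vec& conc, const arma::ivec& dv,
                        const arma::ivec& obs_ptr,
                        double ec50, double gamma, double om2,
                        const arma::vec& eta_init, int n_nodes = 15) {
  int n = obs_ptr.n_elem - 1;
  bool active = om2 > 1e-12;
  double log_ec50 = std::log(ec50);
  arma::vec eta_out(n, arma::fill::zeros), contrib(n);
  LogicalVector okv(n);
  arma::vec nodes, weights;
  if (active) gh_rule(n_nodes, nodes, weights);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    PdSubject s;
    s.conc = conc.subvec(obs_ptr[i], obs_ptr[i + 1] - 1);
    s.dv = dv.subvec(obs_ptr[i], obs_ptr[i + 1] - 1);
    ObjFn g = [&](const arma::vec& e) {
      return pd_g(e, s, active, om2, log_ec50, gamma);
    };
    double ci;
    bool ok = true;
    if (!active) {
      arma::vec e0;
      ci = 2.0 * g(e0);
    } else {
      arma::vec eta(1);
      eta[0] = eta_init[i];
      double gmin = inner_newton(g, eta, ok);
      if (!ok) {
        arma::vec eta2(1, arma::fill::zeros);
        bool ok2;
        double g2 = inner_newton(g, eta2, ok2);
        if (g2 < gmin) { gmin = g2; eta = eta2; ok = ok2; }
      }
      bool pd_;
      double ld = logdet_hess(g, eta, pd_);
      if (!std::isfinite(ld)) {  // fall back to prior curvature
        ok = false;
        ld = -std::log(om2);
      }
      // scale from the mode curvature: s = H^{-1/2}
      double s_scale = std::exp(-0.5 * ld);
      arma::vec e1(1);
      double lse = -arma::datum::inf;
      arma::vec terms(n_nodes);
      for (int k = 0; k < n_nodes; ++k) {
        e1[0] = eta[0] + std::sqrt(2.0) * s_scale * nodes[k];
        terms[k] = std::log(weights[k]) + nodes[k] * nodes[k] - g(e1);
        if (terms[k] > lse) lse = terms[k];
      }
      double acc = 0.0;
      for (int k = 0; k < n_nodes; ++k) acc += std::exp(terms[k] - lse);
      double logL = 0.5 * std::log(2.0) + std::log(s_scale) + lse +
        std::log(acc);
      ci = -2.0 * logL;
      eta_out[i] = eta[0];
    }
    contrib[i] = ci;
    okv[i] = ok;
    total += ci;
  }
  return List::create(_["ofv"] = total, _["contrib"] = contrib,
                      _["eta"] = eta_out, _["ok"] = okv);
}
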