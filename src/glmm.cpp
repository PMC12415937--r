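// Likelihood core for the hierarchical models and small image utilities.
//
// The Tweedie (1 < p < 2) density is evaluated through its compound
// Poisson-gamma series; the zero-inflated Beta and Tweedie marginal
// likelihoods integrate nested mouse/image Gaussian random intercepts by a
// Laplace approximation around the per-mouse joint mode (inner Newton
// iterations, tolerance 1e-8).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// Tweedie compound Poisson-gamma: mu-free series normaliser
//
// f(y) = exp(t(mu)) * sum_{n>=1} c_n(y, phi, p)  for y > 0, where
//   t(mu) = (y mu^{1-p}/(1-p) - mu^{2-p}/(2-p)) / phi
//   log c_n = n log z + (n a - 1) log y - lgamma(n+1) - lgamma(n a),
//   a = (2-p)/(p-1),  z = 1 / (phi^{1+a} (2-p) (p-1)^a).
// The dominant index is near jmax = y^{2-p} / (phi (2-p)); terms are summed
// outward from there until they fall 37 log-units below the maximum.
static double tw_log_series(double y, double phi, double p) {
  const double a = (2.0 - p) / (p - 1.0);
  const double logz = -(1.0 + a) * std::log(phi) - std::log(2.0 - p) -
                      a * std::log(p - 1.0);
  const double logy = std::log(y);
  double jmax = std::pow(y, 2.0 - p) / (phi * (2.0 - p));
  long n0 = (long)std::lround(jmax);
  if (n0 < 1) n0 = 1;
  auto logc = [&](long n) {
    return n * logz + (n * a - 1.0) * logy - std::lgamma((double)n + 1.0) -
           std::lgamma(n * a);
  };
  const double drop = 37.0;
  double lmax = logc(n0);
  // expand upward
  std::vector<double> terms;
  terms.push_back(lmax);
  for (long n = n0 + 1; n < n0 + 100000; ++n) {
    double lt = logc(n);
    terms.push_back(lt);
    if (lt > lmax) lmax = lt;
    if (lt < lmax - drop) break;
  }
  for (long n = n0 - 1; n >= 1; --n) {
    double lt = logc(n);
    terms.push_back(lt);
    if (lt > lmax) lmax = lt;
    if (lt < lmax - drop) break;
  }
  double s = 0.0;
  for (double lt : terms) s += std::exp(lt - lmax);
  return lmax + std::log(s);
}

// [[Rcpp::export]]
NumericVector cpp_tweedie_logdens(NumericVector y, NumericVector mu,
                                  double phi, double p) {
  if (!(p > 1.0 && p < 2.0)) stop("power p must lie in (1, 2)");
  if (!(phi > 0)) stop("dispersion phi must be positive");
  R_xlen_t n = y.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mui = mu[mu.size() == n ? i : 0];
    if (!(mui > 0)) stop("mu must be positive");
    double lambda = std::pow(mui, 2.0 - p) / (phi * (2.0 - p));
    if (y[i] < 0) {
      out[i] = R_NegInf;
    } else if (y[i] == 0) {
      out[i] = -lambda;
    } else {
      double t = (y[i] * std::pow(mui, 1.0 - p) / (1.0 - p) -
                  std::pow(mui, 2.0 - p) / (2.0 - p)) / phi;
      out[i] = t + tw_log_series(y[i], phi, p);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-observation log-density value + first two derivatives w.r.t. the
// linear predictor eta (mu-link: logit for the Beta mean, log for Tweedie).

struct ObsDeriv { double l, d1, d2; };

// Beta part of the zero-inflated model, for y in (0,1):
//   mu = plogis(eta), shapes (mu phi, (1-mu) phi)
static inline ObsDeriv zib_obs(double y, double eta, double phi,
                               double logy, double log1my) {
  if (eta > 30.0) eta = 30.0; else if (eta < -30.0) eta = -30.0;
  double mu = 1.0 / (1.0 + std::exp(-eta));
  double aa = mu * phi, bb = (1.0 - mu) * phi;
  ObsDeriv o;
  o.l = std::lgamma(phi) - std::lgamma(aa) - std::lgamma(bb) +
        (aa - 1.0) * logy + (bb - 1.0) * log1my;
  double mp = mu * (1.0 - mu);
  double g0 = logy - log1my - R::digamma(aa) + R::digamma(bb);
  o.d1 = phi * mp * g0;
  o.d2 = phi * mp * (1.0 - 2.0 * mu) * g0 -
         phi * phi * mp * mp * (R::trigamma(aa) + R::trigamma(bb));
  return o;
}

// Tweedie, mu = exp(eta); series constant passed in (0 for y == 0)
static inline ObsDeriv tw_obs(double y, double eta, double phi, double p,
                              double log_series) {
  if (eta > 30.0) eta = 30.0; else if (eta < -30.0) eta = -30.0;
  double e1 = std::exp((1.0 - p) * eta);   // mu^{1-p}
  double e2 = std::exp((2.0 - p) * eta);   // mu^{2-p}
  ObsDeriv o;
  if (y == 0) {
    o.l = -e2 / (phi * (2.0 - p));
  } else {
    o.l = (y * e1 / (1.0 - p) - e2 / (2.0 - p)) / phi + log_series;
  }
  o.d1 = (y * e1 - e2) / phi;
  o.d2 = ((1.0 - p) * y * e1 - (2.0 - p) * e2) / phi;
  return o;
}

// ---------------------------------------------------------------------------
// Warm-start cache shared across objective evaluations of one fit: the
// random-effect modes of the previous evaluation and the Tweedie series
// constants of the previous (phi, p).

struct GlmmCache {
  std::vector<double> u, v;      // per-mouse / per-image modes
  std::vector<double> lser;      // per-observation series constants
  double phi = -1.0, p = -1.0;
};

// [[Rcpp::export]]
SEXP cpp_glmm_cache() {
  return XPtr<GlmmCache>(new GlmmCache(), true);
}

// ---------------------------------------------------------------------------
// Laplace-approximated marginal negative log-likelihood.
//
// family: 1 = zero-inflated Beta (zero part has no random effects, handled
//             on fixed effects only), 2 = Tweedie.
// offset:   X beta per observation (mu linear predictor, fixed part)
// zi_lp:    zero-part linear predictor per observation (family 1 only)
// mouse:    0-based mouse index per observation
// image:    0-based global image index per observation
// Random intercepts: mouse-level sd sig_m, image-level sd sig_i; an sd below
// 1e-8 removes that level (dimension dropped; exact, not approximate).
// cache: optional XPtr from cpp_glmm_cache() to warm-start the inner
// Newton iterations across evaluations.

// [[Rcpp::export]]
double cpp_glmm_nll(NumericVector y, NumericVector offset, NumericVector zi_lp,
                    IntegerVector mouse, IntegerVector image,
                    int n_mouse, int n_image,
                    double phi, double p, double sig_m, double sig_i,
                    int family, SEXP cache = R_NilValue) {
  const R_xlen_t n = y.size();
  const bool zib = (family == 1);
  if (!(phi > 0)) return NA_REAL;
  if (!zib && !(p > 1.0 && p < 2.0)) return NA_REAL;

  GlmmCache* C = nullptr;
  if (cache != R_NilValue) {
    XPtr<GlmmCache> xp(cache);
    C = xp.get();
    if ((int)C->u.size() != n_mouse) C->u.assign(n_mouse, 0.0);
    if ((int)C->v.size() != n_image) C->v.assign(n_image, 0.0);
  }

  double ll_const = 0.0;             // parts independent of random effects
  std::vector<bool> active(n, true); // obs entering the RE-dependent part
  std::vector<double> logy(n, 0.0), log1my(n, 0.0);
  std::vector<double> lser_local;
  const std::vector<double>* lser = &lser_local;

  if (zib) {
    lser_local.assign(n, 0.0);
    for (R_xlen_t i = 0; i < n; ++i) {
      double zlp = zi_lp[i];
      if (zlp > 30.0) zlp = 30.0; else if (zlp < -30.0) zlp = -30.0;
      // log pi and log(1-pi) via log1p(exp(.)) stable forms
      double lpi = -std::log1p(std::exp(-zlp));
      double l1mpi = -std::log1p(std::exp(zlp));
      if (y[i] <= 0.0) {
        ll_const += lpi;
        active[i] = false;
      } else {
        if (y[i] >= 1.0) return NA_REAL;  // caller must squeeze first
        ll_const += l1mpi;
        logy[i] = std::log(y[i]);
        log1my[i] = std::log1p(-y[i]);
      }
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) if (y[i] < 0) return NA_REAL;
    if (C && C->phi == phi && C->p == p && (R_xlen_t)C->lser.size() == n) {
      lser = &C->lser;   // same (phi, p): reuse series constants
    } else {
      lser_local.assign(n, 0.0);
      for (R_xlen_t i = 0; i < n; ++i)
        if (y[i] > 0) lser_local[i] = tw_log_series(y[i], phi, p);
      if (C) { C->lser = lser_local; C->phi = phi; C->p = p; }
    }
  }

  const bool has_u = sig_m > 1e-8;
  const bool has_v = sig_i > 1e-8;

  // group observations by mouse; local image indexing within mouse
  std::vector<std::vector<int>> obs_of_mouse(n_mouse);
  for (R_xlen_t i = 0; i < n; ++i) obs_of_mouse[mouse[i]].push_back(i);

  double ll = ll_const;

  for (int m = 0; m < n_mouse; ++m) {
    const std::vector<int>& idx = obs_of_mouse[m];
    if (idx.empty()) continue;

    // local image ids for this mouse (only if image effects active)
    std::vector<int> loc(idx.size(), -1);
    int J = 0;
    if (has_v) {
      std::map<int, int> remap;
      for (size_t k = 0; k < idx.size(); ++k) {
        int g = image[idx[k]];
        auto it = remap.find(g);
        if (it == remap.end()) { remap[g] = J; loc[k] = J; ++J; }
        else loc[k] = it->second;
      }
    }
    const int d = (has_u ? 1 : 0) + J;

    if (d == 0) {
      for (size_t k = 0; k < idx.size(); ++k) {
        int i = idx[k];
        ObsDeriv o = zib ? (active[i]
                              ? zib_obs(y[i], offset[i], phi, logy[i], log1my[i])
                              : ObsDeriv{0.0, 0.0, 0.0})
                         : tw_obs(y[i], offset[i], phi, p, (*lser)[i]);
        ll += o.l;
      }
      continue;
    }

    // inner Newton over w = (u, v_1..v_J); minimise f(w) = -joint loglik.
    // Steps use a positive-definite surrogate (per-observation curvature
    // clipped at zero, the Beta log-likelihood being non-concave in
    // places); the log-determinant uses the true Hessian at the mode.
    arma::vec w(d, arma::fill::zeros);
    if (C) {
      if (has_u) w[0] = C->u[m];
      if (J > 0) {
        // recover each local image's global id via its first observation
        std::vector<int> gimg(J, -1);
        for (size_t k = 0; k < idx.size(); ++k)
          if (gimg[loc[k]] < 0) gimg[loc[k]] = image[idx[k]];
        for (int j = 0; j < J; ++j) w[(has_u ? 1 : 0) + j] = C->v[gimg[j]];
      }
    }
    arma::vec prec(d);
    if (has_u) prec[0] = 1.0 / (sig_m * sig_m);
    for (int j = 0; j < J; ++j) prec[(has_u ? 1 : 0) + j] = 1.0 / (sig_i * sig_i);

    // hess: true Hessian of f; hpd: PD surrogate used for step direction
    auto eval = [&](const arma::vec& ww, arma::vec* grad, arma::mat* hess,
                    arma::mat* hpd, double* sum_l) -> double {
      double f = 0.0, sl = 0.0;
      if (grad) grad->zeros();
      if (hess) hess->zeros();
      if (hpd) hpd->zeros();
      for (size_t k = 0; k < idx.size(); ++k) {
        int i = idx[k];
        if (zib && !active[i]) continue;
        double eta = offset[i];
        if (has_u) eta += ww[0];
        int jv = -1;
        if (J > 0) { jv = (has_u ? 1 : 0) + loc[k]; eta += ww[jv]; }
        ObsDeriv o = zib ? zib_obs(y[i], eta, phi, logy[i], log1my[i])
                         : tw_obs(y[i], eta, phi, p, (*lser)[i]);
        sl += o.l;
        f -= o.l;
        if (grad) {
          if (has_u) (*grad)[0] -= o.d1;
          if (jv >= 0) (*grad)[jv] -= o.d1;
        }
        double c_true = -o.d2;
        double c_pd = c_true > 0.0 ? c_true : 0.0;
        if (hess) {
          if (has_u) (*hess)(0, 0) += c_true;
          if (jv >= 0) {
            (*hess)(jv, jv) += c_true;
            if (has_u) { (*hess)(0, jv) += c_true; (*hess)(jv, 0) += c_true; }
          }
        }
        if (hpd) {
          if (has_u) (*hpd)(0, 0) += c_pd;
          if (jv >= 0) {
            (*hpd)(jv, jv) += c_pd;
            if (has_u) { (*hpd)(0, jv) += c_pd; (*hpd)(jv, 0) += c_pd; }
          }
        }
      }
      for (int k2 = 0; k2 < d; ++k2) {
        f += 0.5 * ww[k2] * ww[k2] * prec[k2];
        if (grad) (*grad)[k2] += ww[k2] * prec[k2];
        if (hess) (*hess)(k2, k2) += prec[k2];
        if (hpd) (*hpd)(k2, k2) += prec[k2];
      }
      if (sum_l) *sum_l = sl;
      return f;
    };

    arma::vec grad(d);
    arma::mat H(d, d), Hpd(d, d);
    double sum_l = 0.0;
    double f = eval(w, &grad, &H, &Hpd, &sum_l);
    if (!std::isfinite(f)) {  // bad warm start: retry from zero
      w.zeros();
      f = eval(w, &grad, &H, &Hpd, &sum_l);
      if (!std::isfinite(f)) return NA_REAL;
    }

    for (int iter = 0; iter < 60; ++iter) {
      if (arma::norm(grad, "inf") < 1e-8) break;
      // prefer the true Hessian (quadratic convergence near the mode);
      // fall back to the PD surrogate away from it
      arma::vec step;
      bool ok = false;
      arma::mat R;
      if (arma::chol(R, H)) {
        step = arma::solve(arma::trimatu(R),
                           arma::solve(arma::trimatl(R.t()), grad));
        ok = true;
      }
      if (!ok && !arma::solve(step, Hpd, grad,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx)) {
        arma::mat Hr = Hpd;
        Hr.diag() += 1e-8 + 1e-8 * arma::norm(grad, "inf");
        if (!arma::solve(step, Hr, grad)) return NA_REAL;
      }
      double t = 1.0;
      bool accepted = false;
      for (int ls = 0; ls < 40; ++ls) {
        arma::vec wn = w - t * step;
        double fn = eval(wn, nullptr, nullptr, nullptr, nullptr);
        if (std::isfinite(fn) && fn < f) { w = wn; accepted = true; break; }
        t *= 0.5;
      }
      if (!accepted) break;  // stationary within line-search resolution
      f = eval(w, &grad, &H, &Hpd, &sum_l);
      if (!std::isfinite(f)) return NA_REAL;
    }

    if (C) {
      if (has_u) C->u[m] = w[0];
      if (J > 0) {
        std::vector<int> gimg(J, -1);
        for (size_t k = 0; k < idx.size(); ++k)
          if (gimg[loc[k]] < 0) gimg[loc[k]] = image[idx[k]];
        for (int j = 0; j < J; ++j) C->v[gimg[j]] = w[(has_u ? 1 : 0) + j];
      }
    }

    // g(w_hat) = sum_l + sum_k log dnorm(w_k; 0, sd_k)
    double g = sum_l;
    for (int k2 = 0; k2 < d; ++k2)
      g += -0.5 * LOG2PI + 0.5 * std::log(prec[k2]) -
           0.5 * w[k2] * w[k2] * prec[k2];

    double ldet, sign;
    if (!arma::log_det(ldet, sign, H) || sign <= 0) {
      // true Hessian not PD at the found point: fall back to the PD
      // surrogate so the objective stays continuous for the outer search
      if (!arma::log_det(ldet, sign, Hpd) || sign <= 0) return NA_REAL;
    }
    ll += g + 0.5 * d * LOG2PI - 0.5 * ldet;
  }

  if (!std::isfinite(ll)) return NA_REAL;
  return -ll;
}

// ---------------------------------------------------------------------------
// Connected-component labelling with selectable 4- or 8-connectivity
// (two-pass union-find; row-major scan).

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int left = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      int dul = 0, dur = 0;
      if (connectivity == 8) {
        dul = (r > 0 && c > 0 && mask(r - 1, c - 1)) ? lab(r - 1, c - 1) : 0;
        dur = (r < nr - 1 && c > 0 && mask(r + 1, c - 1)) ? lab(r + 1, c - 1) : 0;
      }
      int nb[4] = {up, left, dul, dur};
      int assigned = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0) { assigned = assigned ? std::min(assigned, nb[k]) : nb[k]; }
      if (assigned == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        lab(r, c) = assigned;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) unite(assigned, nb[k]);
      }
    }
  }
  // second pass: flatten + relabel densely
  std::vector<int> dense(next + 1, 0);
  int nlab = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (dense[root] == 0) dense[root] = ++nlab;
        lab(r, c) = dense[root];
      }
  return lab;
}
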