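#include "bhm_model.h"
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;
using dietbhm::BhmModel;

// No-U-Turn sampler with multinomial trajectory sampling, dual-averaging
// step-size adaptation and windowed diagonal-metric adaptation.  One chain
// per call; randomness comes from R's RNG so chains are reproducible with
// set.seed() on the R side.

namespace {

struct Target {
  BhmModel* bhm;
  Rcpp::Function* rfun;
  int P;
  long n_evals = 0;

  double lp_grad(const std::vector<double>& q, std::vector<double>& g) {
    ++n_evals;
    if (bhm) return bhm->lp_grad(q.data(), g.data());
    NumericVector qv(q.begin(), q.end());
    List res = (*rfun)(qv);
    double lp = as<double>(res["lp"]);
    NumericVector gv = res["grad"];
    if ((int)gv.size() != P) stop("gradient length mismatch");
    for (int k = 0; k < P; ++k) g[k] = gv[k];
    if (!std::isfinite(lp)) {
      std::fill(g.begin(), g.end(), 0.0);
      return -INFINITY;
    }
    return lp;
  }
};

struct Point {
  std::vector<double> q, p, g;
  double lp;
};

struct Sampler {
  Target* tgt;
  int P;
  // block-diagonal inverse metric (estimated posterior covariance):
  // scalar entries for most coordinates plus 2x2 blocks for declared
  // coordinate pairs (e.g. per-OTU intercept/slope), which whitens the
  // dominant pairwise posterior correlations a diagonal metric cannot.
  std::vector<double> inv_metric;      // scalar part
  std::vector<int> pa, pb;             // pair member indices (0-based)
  std::vector<int> pair_of;            // per coordinate: pair id or -1
  std::vector<double> S11, S12, S22;   // per pair: inverse-metric block
  std::vector<double> vws;             // velocity workspace
  double eps;
  int max_depth;
  double delta;
  // per-iteration tallies
  double accept_sum;
  int n_leapfrog, depth_taken;
  bool divergent;

  void set_pairs(const std::vector<int>& a, const std::vector<int>& b) {
    pa = a;
    pb = b;
    pair_of.assign(P, -1);
    for (size_t r = 0; r < pa.size(); ++r) {
      if (pa[r] < 0 || pa[r] >= P || pb[r] < 0 || pb[r] >= P ||
          pa[r] == pb[r] || pair_of[pa[r]] >= 0 || pair_of[pb[r]] >= 0)
        Rcpp::stop("invalid metric pair specification");
      pair_of[pa[r]] = (int)r;
      pair_of[pb[r]] = (int)r;
    }
    S11.assign(pa.size(), 1.0);
    S12.assign(pa.size(), 0.0);
    S22.assign(pa.size(), 1.0);
    vws.assign(P, 0.0);
  }

  // v = M^{-1} p
  void vel(const std::vector<double>& p, std::vector<double>& v) const {
    for (int k = 0; k < P; ++k)
      if (pair_of[k] < 0) v[k] = inv_metric[k] * p[k];
    for (size_t r = 0; r < pa.size(); ++r) {
      const int i = pa[r], j = pb[r];
      v[i] = S11[r] * p[i] + S12[r] * p[j];
      v[j] = S12[r] * p[i] + S22[r] * p[j];
    }
  }

  void sample_momentum(Point& z) {
    for (int k = 0; k < P; ++k)
      if (pair_of[k] < 0) z.p[k] = norm_rand() / std::sqrt(inv_metric[k]);
    for (size_t r = 0; r < pa.size(); ++r) {
      // p ~ N(0, Sigma^{-1}) with Sigma = L L': p = L^{-T} z
      const double l11 = std::sqrt(S11[r]);
      const double l21 = S12[r] / l11;
      const double l22 = std::sqrt(std::max(S22[r] - l21 * l21, 1e-12));
      const double z1 = norm_rand(), z2 = norm_rand();
      const double pj = z2 / l22;
      z.p[pb[r]] = pj;
      z.p[pa[r]] = (z1 - l21 * pj) / l11;
    }
  }

  void leapfrog(Point& z) {
    for (int k = 0; k < P; ++k) z.p[k] += 0.5 * eps * z.g[k];
    vel(z.p, vws);
    for (int k = 0; k < P; ++k) z.q[k] += eps * vws[k];
    z.lp = tgt->lp_grad(z.q, z.g);
    for (int k = 0; k < P; ++k) z.p[k] += 0.5 * eps * z.g[k];
  }

  double kinetic(const Point& z) const {
    double ke = 0.0;
    for (int k = 0; k < P; ++k)
      if (pair_of[k] < 0) ke += inv_metric[k] * z.p[k] * z.p[k];
    for (size_t r = 0; r < pa.size(); ++r) {
      const double pi = z.p[pa[r]], pj = z.p[pb[r]];
      ke += S11[r] * pi * pi + 2.0 * S12[r] * pi * pj + S22[r] * pj * pj;
    }
    return 0.5 * ke;
  }

  // U-turn check between trajectory endpoints (velocity space)
  bool uturn(const Point& zm, const Point& zp) const {
    double sm = 0.0, sp = 0.0;
    for (int k = 0; k < P; ++k) {
      if (pair_of[k] >= 0) continue;
      const double dq = zp.q[k] - zm.q[k];
      sm += dq * inv_metric[k] * zm.p[k];
      sp += dq * inv_metric[k] * zp.p[k];
    }
    for (size_t r = 0; r < pa.size(); ++r) {
      const int i = pa[r], j = pb[r];
      const double dqi = zp.q[i] - zm.q[i], dqj = zp.q[j] - zm.q[j];
      sm += dqi * (S11[r] * zm.p[i] + S12[r] * zm.p[j]) +
            dqj * (S12[r] * zm.p[i] + S22[r] * zm.p[j]);
      sp += dqi * (S11[r] * zp.p[i] + S12[r] * zp.p[j]) +
            dqj * (S12[r] * zp.p[i] + S22[r] * zp.p[j]);
    }
    return (sm < 0.0) || (sp < 0.0);
  }

  struct Tree {
    Point minus, plus, prop;
    double logw;
    bool ok; // no divergence, no internal U-turn
  };

  // Build a subtree of 2^depth leapfrog steps starting from z in direction
  // dir; z is the endpoint the doubling proceeds from.
  Tree build(int depth, const Point& z, int dir, double H0) {
    if (depth == 0) {
      Tree t;
      t.minus = z;
      const double e0 = eps;
      eps = dir * std::fabs(eps);
      leapfrog(t.minus);
      eps = e0;
      ++n_leapfrog;
      double H = std::isfinite(t.minus.lp) ? -t.minus.lp + kinetic(t.minus)
                                           : INFINITY;
      double dH = H0 - H; // log weight of the new point
      bool div = !std::isfinite(H) || (H - H0 > 1000.0);
      accept_sum += dH > 0.0 ? 1.0 : std::exp(dH);
      t.plus = t.minus;
      t.prop = t.minus;
      t.logw = div ? -INFINITY : dH;
      t.ok = !div;
      divergent = divergent || div;
      return t;
    }
    Tree t1 = build(depth - 1, z, dir, H0);
    if (!t1.ok) return t1;
    Tree t2 = build(depth - 1, dir > 0 ? t1.plus : t1.minus, dir, H0);
    Tree t;
    t.minus = dir > 0 ? t1.minus : t2.minus;
    t.plus = dir > 0 ? t2.plus : t1.plus;
    t.logw = std::max(t1.logw, t2.logw) +
             std::log(std::exp(t1.logw - std::max(t1.logw, t2.logw)) +
                      std::exp(t2.logw - std::max(t1.logw, t2.logw)));
    // multinomial sampling within the subtree
    t.prop = (std::log(unif_rand()) < t2.logw - t.logw) ? t2.prop : t1.prop;
    t.ok = t2.ok && !uturn(t.minus, t.plus);
    return t;
  }

  // One NUTS transition; updates z in place, returns energy at start.
  double transition(Point& z) {
    sample_momentum(z);
    const double H0 = -z.lp + kinetic(z);
    Tree tree;
    tree.minus = z;
    tree.plus = z;
    tree.prop = z;
    tree.logw = 0.0;
    tree.ok = true;
    accept_sum = 0.0;
    n_leapfrog = 0;
    depth_taken = 0;
    divergent = false;
    for (int depth = 0; depth < max_depth; ++depth) {
      const int dir = unif_rand() < 0.5 ? -1 : 1;
      Tree sub = build(depth, dir > 0 ? tree.plus : tree.minus, dir, H0);
      if (!sub.ok) break;
      // biased progressive sampling toward the new subtree
      if (std::log(unif_rand()) < sub.logw - tree.logw) tree.prop = sub.prop;
      const double m = std::max(tree.logw, sub.logw);
      tree.logw = m + std::log(std::exp(tree.logw - m) + std::exp(sub.logw - m));
      if (dir > 0)
        tree.plus = sub.plus;
      else
        tree.minus = sub.minus;
      depth_taken = depth + 1;
      if (uturn(tree.minus, tree.plus)) break;
    }
    z = tree.prop;
    return H0;
  }
};

// double/halve a trial step size until the one-step acceptance probability
// crosses 1/2 (Hoffman & Gelman heuristic)
double init_stepsize(Sampler& s, const Point& z0) {
  Point z = z0;
  s.sample_momentum(z);
  const double H0 = -z.lp + s.kinetic(z);
  auto log_accept = [&](double e) {
    Point zt = z;
    s.eps = e;
    s.leapfrog(zt);
    return std::isfinite(zt.lp) ? (H0 - (-zt.lp + s.kinetic(zt)))
                                : -INFINITY;
  };
  double eps = 1.0;
  const bool grow = log_accept(eps) > std::log(0.5);
  for (int iter = 0; iter < 100; ++iter) {
    if (grow) {
      eps *= 2.0;
      if (log_accept(eps) <= std::log(0.5)) return eps * 0.5;
    } else {
      eps *= 0.5;
      if (log_accept(eps) > std::log(0.5) || eps < 1e-10) return eps;
    }
  }
  return eps;
}

List run_chain(Target& tgt, NumericVector init, int n_warmup, int n_iter,
               int thin, int max_depth, double delta,
               const std::vector<int>& pairs_a,
               const std::vector<int>& pairs_b) {
  const int P = tgt.P;
  Sampler s;
  s.tgt = &tgt;
  s.P = P;
  s.inv_metric.assign(P, 1.0);
  s.set_pairs(pairs_a, pairs_b);
  s.max_depth = max_depth;
  s.delta = delta;

  Point z;
  z.q.assign(init.begin(), init.end());
  z.p.assign(P, 0.0);
  z.g.assign(P, 0.0);
  z.lp = tgt.lp_grad(z.q, z.g);
  if (!std::isfinite(z.lp))
    stop("log density is not finite at the initial values");

  // seed the metric with finite-difference diagonal curvature at the
  // initial point (clamped); far cheaper than running the first
  // adaptation window under an identity metric
  if (n_warmup >= 20) {
    std::vector<double> q1(z.q), g1(P);
    const double h = 1e-4;
    for (int k = 0; k < P; ++k) {
      q1[k] = z.q[k] + h;
      const double lp1 = tgt.lp_grad(q1, g1);
      q1[k] = z.q[k];
      if (std::isfinite(lp1)) {
        const double curv = std::fabs((g1[k] - z.g[k]) / h);
        double v = 1.0 / std::max(curv, 1.0);
        if (v < 1e-4) v = 1e-4;
        s.inv_metric[k] = v;
      }
    }
    for (size_t r = 0; r < s.pa.size(); ++r) {
      s.S11[r] = s.inv_metric[s.pa[r]];
      s.S22[r] = s.inv_metric[s.pb[r]];
      s.S12[r] = 0.0;
    }
  }

  s.eps = init_stepsize(s, z);

  // dual averaging (Nesterov / Hoffman-Gelman defaults)
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu_da = std::log(10.0 * s.eps), Hbar = 0.0, log_eps_bar = 0.0;
  int m_adapt = 0;

  // metric adaptation windows
  int init_buf = 75, term_buf = 50, base_win = 25;
  if (init_buf + term_buf + base_win > n_warmup) {
    init_buf = (int)std::floor(0.15 * n_warmup);
    term_buf = (int)std::floor(0.10 * n_warmup);
    base_win = n_warmup - init_buf - term_buf;
  }
  std::vector<int> win_ends;
  if (base_win > 0 && n_warmup >= 20) {
    int start = init_buf, w = base_win;
    while (true) {
      int end = start + w;
      if (end + 2 * w > n_warmup - term_buf) end = n_warmup - term_buf;
      win_ends.push_back(end);
      if (end >= n_warmup - term_buf) break;
      start = end;
      w *= 2;
    }
  }
  std::vector<double> wm(P, 0.0), wm2(P, 0.0);
  std::vector<double> wcov(s.pa.size(), 0.0), dpre(s.pa.size(), 0.0);
  long wn = 0;
  size_t win_idx = 0;

  const int n_store = n_iter / thin;
  NumericMatrix draws(n_store, P);
  NumericVector lp_out(n_store), energy(n_store), accept(n_store);
  IntegerVector tdepth(n_store), nlf(n_store), div(n_store);
  IntegerVector warm_nlf(n_warmup);
  int n_div_sampling = 0;

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    const bool warm = it < n_warmup;
    double H0 = s.transition(z);
    const double astat =
        s.n_leapfrog > 0 ? s.accept_sum / s.n_leapfrog : 0.0;
    if (warm) {
      warm_nlf[it] = s.n_leapfrog;
      ++m_adapt;
      Hbar = (1.0 - 1.0 / (m_adapt + t0)) * Hbar +
             (delta - astat) / (m_adapt + t0);
      double log_eps = mu_da - std::sqrt((double)m_adapt) / gamma * Hbar;
      double eta = std::pow((double)m_adapt, -kappa);
      log_eps_bar = eta * log_eps + (1.0 - eta) * log_eps_bar;
      s.eps = std::exp(log_eps);
      // accumulate for the metric after the initial buffer
      if (it >= init_buf && win_idx < win_ends.size()) {
        for (size_t r = 0; r < s.pa.size(); ++r)
          dpre[r] = z.q[s.pa[r]] - wm[s.pa[r]];
        ++wn;
        for (int k = 0; k < P; ++k) {
          const double d = z.q[k] - wm[k];
          wm[k] += d / wn;
          wm2[k] += d * (z.q[k] - wm[k]);
        }
        for (size_t r = 0; r < s.pa.size(); ++r)
          wcov[r] += dpre[r] * (z.q[s.pb[r]] - wm[s.pb[r]]);
        if (it + 1 == win_ends[win_idx]) {
          if (wn > 1) {
            const double shrink = (double)wn / (wn + 5.0);
            const double ridge = 1e-3 * (5.0 / (wn + 5.0));
            for (int k = 0; k < P; ++k) {
              double v = shrink * (wm2[k] / (wn - 1)) + ridge;
              s.inv_metric[k] = v;
            }
            for (size_t r = 0; r < s.pa.size(); ++r) {
              const double v1 = s.inv_metric[s.pa[r]];
              const double v2 = s.inv_metric[s.pb[r]];
              double c = shrink * (wcov[r] / (wn - 1));
              const double cap = 0.98 * std::sqrt(v1 * v2);
              if (c > cap) c = cap;
              if (c < -cap) c = -cap;
              s.S11[r] = v1;
              s.S22[r] = v2;
              s.S12[r] = c;
            }
          }
          std::fill(wm.begin(), wm.end(), 0.0);
          std::fill(wm2.begin(), wm2.end(), 0.0);
          std::fill(wcov.begin(), wcov.end(), 0.0);
          wn = 0;
          ++win_idx;
          // restart step-size adaptation around the current average
          s.eps = std::exp(log_eps_bar);
          mu_da = std::log(10.0 * s.eps);
          Hbar = 0.0;
          m_adapt = 0;
        }
      }
      if (it + 1 == n_warmup) s.eps = std::exp(log_eps_bar);
    } else {
      if (s.divergent) ++n_div_sampling;
      const int post = it - n_warmup;
      if ((post + 1) % thin == 0) {
        const int row = post / thin;
        for (int k = 0; k < P; ++k) draws(row, k) = z.q[k];
        lp_out[row] = z.lp;
        energy[row] = H0;
        accept[row] = astat;
        tdepth[row] = s.depth_taken;
        nlf[row] = s.n_leapfrog;
        div[row] = s.divergent ? 1 : 0;
      }
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lp_out, _["energy"] = energy,
      _["accept_stat"] = accept, _["treedepth"] = tdepth,
      _["n_leapfrog"] = nlf, _["divergent"] = div,
      _["warmup_n_leapfrog"] = warm_nlf,
      _["n_divergent"] = n_div_sampling, _["stepsize"] = s.eps,
      _["inv_metric"] = NumericVector(s.inv_metric.begin(), s.inv_metric.end()),
      _["n_evals"] = (double)tgt.n_evals);
}

} // namespace

// [[Rcpp::export]]
List cpp_bhm_lp_grad(NumericVector theta, NumericMatrix Y, NumericVector x,
                     NumericVector logz, IntegerVector fam, int nfam,
                     bool centered) {
  BhmModel m(Y, x, logz, fam, nfam);
  m.centered = centered;
  if ((int)theta.size() != m.P)
    stop("theta has length %d, expected %d", (int)theta.size(), m.P);
  std::vector<double> g(m.P);
  double lp = m.lp_grad(REAL(theta), g.data());
  return List::create(_["lp"] = lp,
                      _["grad"] = NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export]]
int cpp_bhm_n_params(NumericMatrix Y, IntegerVector fam, int nfam) {
  return 4 + 4 * nfam + 1 + 2 * Y.ncol() + 3 + Y.ncol();
}

// [[Rcpp::export]]
List cpp_nuts_bhm(NumericMatrix Y, NumericVector x, NumericVector logz,
                  IntegerVector fam, int nfam, NumericVector init,
                  int n_warmup, int n_iter, int thin, int max_depth,
                  double delta, bool centered) {
  BhmModel m(Y, x, logz, fam, nfam);
  m.centered = centered;
  if ((int)init.size() != m.P)
    stop("init has length %d, expected %d", (int)init.size(), m.P);
  Target tgt;
  tgt.bhm = &m;
  tgt.rfun = nullptr;
  tgt.P = m.P;
  // 2x2 metric blocks: each per-OTU (intercept, slope) pair and the
  // dispersion-trend coefficients (a1, a0)
  const int J = m.J, F4 = 4 + 4 * m.F;
  std::vector<int> a, b;
  for (int j = 0; j < J; ++j) {
    a.push_back(F4 + 1 + j);
    b.push_back(F4 + 1 + J + j);
  }
  a.push_back(F4 + 1 + 2 * J);
  b.push_back(F4 + 2 + 2 * J);
  return run_chain(tgt, init, n_warmup, n_iter, thin, max_depth, delta, a, b);
}

// [[Rcpp::export]]
List cpp_nuts_rfun(Function lp_grad_fn, NumericVector init, int n_warmup,
                   int n_iter, int thin, int max_depth, double delta,
                   IntegerMatrix pairs) {
  Target tgt;
  tgt.bhm = nullptr;
  tgt.rfun = &lp_grad_fn;
  tgt.P = init.size();
  std::vector<int> a, b;
  for (int r = 0; r < pairs.nrow(); ++r) {
    a.push_back(pairs(r, 0) - 1); // R is 1-based
    b.push_back(pairs(r, 1) - 1);
  }
  return run_chain(tgt, init, n_warmup, n_iter, thin, max_depth, delta, a, b);
}
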