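#ifndef DIETBHM_BHM_MODEL_H
#define DIETBHM_BHM_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

#include "fastmath.h"

// Three-level hierarchical negative binomial model, unconstrained
// parameterization used by the sampler.
//
// Parameter vector layout (P = 4 + 4F + 1 + 2J + 3 + J):
//   [0] mu_alpha  [1] mu_beta  [2] log sigma_alpha  [3] log sigma_beta
//   [4, 4+F)      mu_alpha_f
//   [4+F, 4+2F)   mu_beta_f
//   [4+2F, 4+3F)  log sigma_alpha_f
//   [4+3F, 4+4F)  log sigma_beta_f
//   [4+4F]        atanh(omega)
//   next J        coefficient block 1 (see below)
//   next J        coefficient block 2
//   next          a1, a0, log sigma_phi
//   next J        log phi
//
// Coefficient block, centered variant (default): block1 holds the
// intercept at the covariate mean (alpha_j + xbar * beta_j), block2 the
// slope beta_j; the bivariate-normal family prior is evaluated on the
// true (alpha_j, beta_j).  Centering the covariate removes the
// intercept-slope likelihood correlation and is a linear, unit-Jacobian
// reparameterization.
//
// Non-centered variant: block1/block2 hold standard-normal innovations
// (u1_j, u2_j) with alpha_j = mu_alpha_f + sigma_alpha_f * u1_j,
// beta_j = mu_beta_f + sigma_beta_f * (omega*u1_j + sqrt(1-omega^2)*u2_j).
//
// All positive parameters are sampled on the log scale with Jacobian
// corrections; omega via tanh.  The lognormal prior on phi_j combined
// with the log transform reduces to a normal density on log phi_j,
// located on the mean-dispersion trend a1 * mean_i(mu_ij) + a0, which is
// recomputed from the current (alpha, beta) at every evaluation.

namespace dietbhm {

constexpr double LOG_2PI = 1.8378770664093454836;
constexpr int YTAB_CAP = 1024; // per-OTU lookup tables cover y <= cap

class BhmModel {
public:
  int N, J, F, P;
  bool centered = true;
  double xbar = 0.0;
  std::vector<double> y;   // counts, column-major (J columns of length N);
                           // integer-valued but kept as double (counts can
                           // exceed the 32-bit range)
  std::vector<double> x;   // covariate, centered, length N
  std::vector<double> logz;// log library size, length N
  std::vector<int> fam;    // 0-based family index per OTU
  std::vector<int> ycap;   // table extent per OTU
  std::vector<int> toff;   // table offsets
  std::vector<char> hasbig;// any y beyond the table cap?
  // workspace (rebuilt each evaluation; tables depend on current phi_j)
  std::vector<double> lgtab, dgtab, lgyfact;
  std::vector<double> alpha, beta, phi;

  BhmModel(const Rcpp::NumericMatrix& Y, const Rcpp::NumericVector& x_,
           const Rcpp::NumericVector& logz_, const Rcpp::IntegerVector& fam_,
           int nfam)
      : N(Y.nrow()), J(Y.ncol()), F(nfam) {
    P = 4 + 4 * F + 1 + 2 * J + 3 + J;
    y.resize((size_t)N * J);
    double ymax_all = 0;
    ycap.resize(J);
    toff.resize(J + 1);
    toff[0] = 0;
    for (int j = 0; j < J; ++j) {
      double ym = 0;
      for (int i = 0; i < N; ++i) {
        double v = Y(i, j);
        if (!(v >= 0) || v != std::floor(v))
          Rcpp::stop("counts must be non-negative integers");
        y[(size_t)j * N + i] = v;
        if (v > ym) ym = v;
      }
      if (ym > ymax_all) ymax_all = ym;
      ycap[j] = ym < (double)YTAB_CAP ? (int)ym : YTAB_CAP;
      hasbig.push_back(ym > (double)YTAB_CAP ? 1 : 0);
      toff[j + 1] = toff[j] + ycap[j] + 1;
    }
    x.assign(x_.begin(), x_.end());
    xbar = 0.0;
    for (int i = 0; i < N; ++i) xbar += x[i];
    xbar /= N;
    for (int i = 0; i < N; ++i) x[i] -= xbar;
    logz.assign(logz_.begin(), logz_.end());
    fam.resize(J);
    for (int j = 0; j < J; ++j) {
      int f = fam_[j];
      if (f < 1 || f > F) Rcpp::stop("family index out of range");
      fam[j] = f - 1;
    }
    lgtab.resize(toff[J]);
    dgtab.resize(toff[J]);
    int capfact = (ymax_all < (double)YTAB_CAP ? (int)ymax_all : YTAB_CAP) + 1;
    lgyfact.resize(capfact);
    for (int v = 0; v < capfact; ++v) lgyfact[v] = std::lgamma((double)v + 1.0);
    alpha.resize(J);
    beta.resize(J);
    phi.resize(J);
  }

  // log posterior density and gradient; returns -Inf (grad zeroed) on
  // numerical failure so the sampler treats the proposal as divergent.
  double lp_grad(const double* th, double* g) {
    const int F4 = 4 + 4 * F;
    const double mua = th[0], mub = th[1];
    const double lsa = th[2], lsb = th[3];
    const double* muaf = th + 4;
    const double* mubf = th + 4 + F;
    const double* lsaf = th + 4 + 2 * F;
    const double* lsbf = th + 4 + 3 * F;
    const double wraw = th[F4];
    const double* u1 = th + F4 + 1;
    const double* u2 = th + F4 + 1 + J;
    const double a1 = th[F4 + 1 + 2 * J];
    const double a0 = th[F4 + 2 + 2 * J];
    const double lsphi = th[F4 + 3 + 2 * J];
    const double* t = th + F4 + 4 + 2 * J;

    for (int k = 0; k < P; ++k) g[k] = 0.0;
    double* g_muaf = g + 4;
    double* g_mubf = g + 4 + F;
    double* g_lsaf = g + 4 + 2 * F;
    double* g_lsbf = g + 4 + 3 * F;
    double* g_u1 = g + F4 + 1;
    double* g_u2 = g + F4 + 1 + J;
    double* g_t = g + F4 + 4 + 2 * J;

    const double sa = std::exp(lsa), sb = std::exp(lsb);
    const double sphi = std::exp(lsphi), sphi2 = sphi * sphi;
    const double omega = std::tanh(wraw);
    const double comp = std::sqrt(1.0 - omega * omega);
    std::vector<double> saf(F), sbf(F);
    for (int f = 0; f < F; ++f) {
      saf[f] = std::exp(lsaf[f]);
      sbf[f] = std::exp(lsbf[f]);
    }
    for (int j = 0; j < J; ++j) {
      const int f = fam[j];
      if (centered) {
        beta[j] = u2[j];
        alpha[j] = u1[j] - xbar * u2[j];
      } else {
        alpha[j] = muaf[f] + saf[f] * u1[j];
        beta[j] = mubf[f] + sbf[f] * (omega * u1[j] + comp * u2[j]);
      }
      phi[j] = std::exp(t[j]);
    }

    double lp = 0.0, gw_sum = 0.0, g_lsphi_acc = 0.0;

    for (int j = 0; j < J; ++j) {
      const int f = fam[j];
      // likelihood uses the intercept at the covariate mean and centered x
      const double aj = alpha[j] + xbar * beta[j];
      const double bj = beta[j], ph = phi[j], lph = t[j];
      // difference tables: lgamma(phi+y)-lgamma(phi),
      // digamma(phi+y)-digamma(phi), built by recurrence
      double* lg = &lgtab[toff[j]];
      double* dg = &dgtab[toff[j]];
      const int cap = ycap[j];
      lg[0] = 0.0;
      dg[0] = 0.0;
      for (int v = 0; v < cap; ++v) {
        lg[v + 1] = lg[v] + std::log(ph + v);
        dg[v + 1] = dg[v] + 1.0 / (ph + v);
      }
      // constants for counts beyond the table cap (asymptotic series)
      const double lgph = hasbig[j] ? std::lgamma(ph) : 0.0;
      const double dgph = hasbig[j] ? R::digamma(ph) : 0.0;
      const double* yj = &y[(size_t)j * N];
      double llj = 0.0, ga = 0.0, gb = 0.0, gphi = 0.0;
      double sum_mu = 0.0, sum_xmu = 0.0;
      for (int i = 0; i < N; ++i) {
        const double eta = aj + bj * x[i] + logz[i];
        const double mu = std::exp(eta);
        const double yi = yj[i];
        const double pm = ph + mu;
        const double lpm = std::log(pm);
        double lgd, dgd, lfy;
        if (yi <= (double)cap) {
          const int yint = (int)yi;
          lgd = lg[yint];
          dgd = dg[yint];
          lfy = lgyfact[yint];
        } else {
          lgd = lgamma_big(ph + yi) - lgph;
          dgd = digamma_big(ph + yi) - dgph;
          lfy = lgamma_big(yi + 1.0);
        }
        llj += lgd - lfy + ph * lph + yi * eta - (ph + yi) * lpm;
        const double dld = yi - (ph + yi) * mu / pm;
        ga += dld;
        gb += x[i] * dld;
        gphi += dgd + lph + 1.0 - lpm - (ph + yi) / pm;
        sum_mu += mu;
        sum_xmu += x[i] * mu;
      }
      if (!std::isfinite(sum_mu)) {
        for (int k = 0; k < P; ++k) g[k] = 0.0;
        return -INFINITY;
      }
      const double mj = sum_mu / N;
      const double mu_phi = a1 * mj + a0;
      const double dres = t[j] - mu_phi;
      const double r = dres / sphi2;
      lp += llj - 0.5 * LOG_2PI - lsphi - 0.5 * dres * r;
      g_t[j] = ph * gphi - r;
      g[F4 + 1 + 2 * J] += r * mj; // a1
      g[F4 + 2 + 2 * J] += r;      // a0
      g_lsphi_acc += -1.0 + r * dres;
      ga += r * a1 * mj;           // trend location depends on mu_ij
      gb += r * a1 * (sum_xmu / N);
      if (centered) {
        // bivariate-normal family prior evaluated on (alpha_j, beta_j)
        const double oc = 1.0 / (1.0 - omega * omega);
        const double A = (alpha[j] - muaf[f]) / saf[f];
        const double B = (beta[j] - mubf[f]) / sbf[f];
        const double Q = (A * A - 2.0 * omega * A * B + B * B) * oc;
        lp += -LOG_2PI - lsaf[f] - lsbf[f] -
              0.5 * std::log1p(-omega * omega) - 0.5 * Q;
        const double dA = (A - omega * B) * oc / saf[f];
        const double dB = (B - omega * A) * oc / sbf[f];
        g_u1[j] = ga - dA;
        g_u2[j] = gb + xbar * dA - dB; // prior acts on alpha = u1 - xbar*u2
        g_muaf[f] += dA;
        g_mubf[f] += dB;
        g_lsaf[f] += -1.0 + (A * A - omega * A * B) * oc;
        g_lsbf[f] += -1.0 + (B * B - omega * A * B) * oc;
        gw_sum += omega * oc - 0.5 * (-2.0 * A * B + 2.0 * omega * Q) * oc;
      } else {
        // back to (alpha, beta) coordinates, then through the
        // non-centered family structure
        const double gb_ab = xbar * ga + gb;
        g_muaf[f] += ga;
        g_mubf[f] += gb_ab;
        g_lsaf[f] += ga * saf[f] * u1[j];
        g_lsbf[f] += gb_ab * sbf[f] * (omega * u1[j] + comp * u2[j]);
        g_u1[j] = ga * saf[f] + gb_ab * sbf[f] * omega - u1[j];
        g_u2[j] = gb_ab * sbf[f] * comp - u2[j];
        gw_sum += gb_ab * sbf[f] * (u1[j] - (omega / comp) * u2[j]);
        lp += -LOG_2PI - 0.5 * (u1[j] * u1[j] + u2[j] * u2[j]);
      }
    }

    const double sa2 = sa * sa, sb2 = sb * sb;
    for (int f = 0; f < F; ++f) {
      const double da = muaf[f] - mua, db = mubf[f] - mub;
      lp += -0.5 * LOG_2PI - lsa - 0.5 * da * da / sa2;
      lp += -0.5 * LOG_2PI - lsb - 0.5 * db * db / sb2;
      g_muaf[f] += -da / sa2;
      g_mubf[f] += -db / sb2;
      g[0] += da / sa2;
      g[1] += db / sb2;
      g[2] += -1.0 + da * da / sa2;
      g[3] += -1.0 + db * db / sb2;
      lp += -saf[f] + lsaf[f]; // Exponential(1) + log Jacobian
      g_lsaf[f] += -saf[f] + 1.0;
      lp += -sbf[f] + lsbf[f];
      g_lsbf[f] += -sbf[f] + 1.0;
    }
    // hyperpriors
    lp += -0.5 * LOG_2PI - 0.5 * mua * mua;
    lp += -0.5 * LOG_2PI - 0.5 * mub * mub;
    g[0] += -mua;
    g[1] += -mub;
    lp += -sa + lsa;
    g[2] += -sa + 1.0;
    lp += -sb + lsb;
    g[3] += -sb + 1.0;
    lp += -0.5 * LOG_2PI - 0.5 * a1 * a1;
    lp += -0.5 * LOG_2PI - 0.5 * a0 * a0;
    g[F4 + 1 + 2 * J] += -a1;
    g[F4 + 2 + 2 * J] += -a0;
    lp += -sphi + lsphi;
    g[F4 + 3 + 2 * J] = g_lsphi_acc - sphi + 1.0;
    // omega ~ Uniform(-1, 1), tanh transform
    lp += std::log(0.5) + std::log1p(-omega * omega);
    g[F4] = (1.0 - omega * omega) * gw_sum - 2.0 * omega;

    if (!std::isfinite(lp)) {
      for (int k = 0; k < P; ++k) g[k] = 0.0;
      return -INFINITY;
    }
    return lp;
  }
};

} // namespace dietbhm

#endif
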