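#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Chinese-restaurant-process mixture of
// diagonal Gaussians over sample dimensions with a Normal-Gamma conjugate
// prior (mu0 = 0, precision scale lambda0, shape a0, rate b0) on every
// dimension. Genes are rows of X (already standardized in R); the sweep
// order is the row order of X (caller sorts by gene id) and the categorical
// draw for gene g at iteration t consumes the pre-drawn uniform U(t, g), so
// the chain is reproducible and independent of input file order.

namespace {

struct ClusterStats {
  int n = 0;
  std::vector<double> sum, sumsq;
  explicit ClusterStats(int S) : sum(S, 0.0), sumsq(S, 0.0) {}
};

// log predictive density of profile x under a module's collapsed posterior
double log_predictive(const double *x, int S, const ClusterStats *m,
                      double lambda0, double a0, double b0) {
  double out = 0.0;
  const int n = m ? m->n : 0;
  const double lambdan = lambda0 + n;
  const double an = a0 + 0.5 * n;
  const double scale_factor = (lambdan + 1.0) / (an * lambdan);
  const double lg = std::lgamma(an + 0.5) - std::lgamma(an);
  const double df = 2.0 * an;
  for (int d = 0; d < S; ++d) {
    double mun = 0.0, bn = b0;
    if (n > 0) {
      const double s = m->sum[d], q = m->sumsq[d];
      const double xbar = s / n;
      double ss = q - s * s / n;
      if (ss < 0) ss = 0;
      mun = s / lambdan;
      bn = b0 + 0.5 * ss + 0.5 * lambda0 * n * xbar * xbar / lambdan;
    }
    const double sigma2 = bn * scale_factor;
    const double z = x[d] - mun;
    out += lg - 0.5 * std::log(df * M_PI * sigma2)
         - (an + 0.5) * std::log1p(z * z / (df * sigma2));
  }
  return out;
}

// log marginal likelihood of all observations currently in a module
double log_marginal(const ClusterStats &m, int S,
                    double lambda0, double a0, double b0) {
  if (m.n == 0) return 0.0;
  const int n = m.n;
  const double lambdan = lambda0 + n;
  const double an = a0 + 0.5 * n;
  double out = 0.0;
  const double base = std::lgamma(an) - std::lgamma(a0) + a0 * std::log(b0)
    + 0.5 * (std::log(lambda0) - std::log(lambdan))
    - 0.5 * n * std::log(2.0 * M_PI);
  for (int d = 0; d < S; ++d) {
    const double s = m.sum[d], q = m.sumsq[d];
    const double xbar = s / n;
    double ss = q - s * s / n;
    if (ss < 0) ss = 0;
    const double bn = b0 + 0.5 * ss + 0.5 * lambda0 * n * xbar * xbar / lambdan;
    out += base - an * std::log(bn);
  }
  return out;
}

double joint_log_posterior(const std::vector<ClusterStats> &mods, int S, int G,
                           double gamma, double lambda0, double a0, double b0) {
  double lp = 0.0;
  int K = 0;
  for (const ClusterStats &m : mods) {
    if (m.n == 0) continue;
    ++K;
    lp += std::lgamma((double)m.n);           // CRP table term (n-1)!
    lp += log_marginal(m, S, lambda0, a0, b0);
  }
  lp += K * std::log(gamma);
  for (int i = 0; i < G; ++i) lp -= std::log(gamma + i);
  return lp;
}

} // namespace

// [[Rcpp::export]]
List gibbs_crp_cpp(NumericMatrix X, NumericMatrix U, double gamma,
                   double lambda0, double a0, double b0,
                   int n_iter, int burn_in) {
  const int G = X.nrow(), S = X.ncol();
  // row-major copy for cache-friendly per-gene access
  std::vector<double> xs((size_t)G * S);
  for (int g = 0; g < G; ++g)
    for (int d = 0; d < S; ++d) xs[(size_t)g * S + d] = X(g, d);

  // start from the all-singletons partition: cluster coalescence is easy
  // for single-site Gibbs moves, nucleating a new cluster out of a large
  // mixed one is not
  std::vector<ClusterStats> mods;
  std::vector<int> z(G, 0);
  for (int g = 0; g < G; ++g) {
    mods.emplace_back(S);
    ClusterStats &m = mods[g];
    m.n = 1;
    const double *x = &xs[(size_t)g * S];
    for (int d = 0; d < S; ++d) { m.sum[d] += x[d]; m.sumsq[d] += x[d] * x[d]; }
    z[g] = g;
  }

  const double init_lp = joint_log_posterior(mods, S, G, gamma, lambda0, a0, b0);
  double best_lp = R_NegInf;
  std::vector<int> best_z = z;
  NumericVector trace(n_iter);
  std::vector<double> logw;

  for (int it = 0; it < n_iter; ++it) {
    for (int g = 0; g < G; ++g) {
      const double *x = &xs[(size_t)g * S];
      // detach gene from its module
      {
        ClusterStats &m = mods[z[g]];
        --m.n;
        for (int d = 0; d < S; ++d) { m.sum[d] -= x[d]; m.sumsq[d] -= x[d] * x[d]; }
        if (m.n == 0) {
          const int dead = z[g];
          mods.erase(mods.begin() + dead);
          for (int h = 0; h < G; ++h) if (z[h] > dead) --z[h];
        }
      }
      const int K = (int)mods.size();
      logw.assign(K + 1, 0.0);
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        logw[k] = std::log((double)mods[k].n)
                + log_predictive(x, S, &mods[k], lambda0, a0, b0);
        if (logw[k] > mx) mx = logw[k];
      }
      logw[K] = std::log(gamma) + log_predictive(x, S, nullptr, lambda0, a0, b0);
      if (logw[K] > mx) mx = logw[K];
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) { logw[k] = std::exp(logw[k] - mx); tot += logw[k]; }
      const double u = U(it, g) * tot;
      double cum = 0.0;
      int pick = K;
      for (int k = 0; k <= K; ++k) { cum += logw[k]; if (u <= cum) { pick = k; break; } }
      if (pick == K) mods.emplace_back(S);
      ClusterStats &m = mods[pick];
      ++m.n;
      for (int d = 0; d < S; ++d) { m.sum[d] += x[d]; m.sumsq[d] += x[d] * x[d]; }
      z[g] = pick;
    }
    const double lp = joint_log_posterior(mods, S, G, gamma, lambda0, a0, b0);
    trace[it] = lp;
    if (it >= burn_in && lp > best_lp) { best_lp = lp; best_z = z; }
  }

  return List::create(_["assignment"] = IntegerVector(best_z.begin(), best_z.end()),
                      _["log_posterior"] = best_lp,
                      _["initial_log_posterior"] = init_lp,
                      _["trace"] = trace);
}
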