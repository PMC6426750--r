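#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Single-site Gibbs sampler for the BayesR four-component normal-mixture
// model  y = X b + Z g + e,  g_j ~ sum_k pi_k N(0, gamma_k * sigma_g2),
// with gamma = (0, 1e-4, 1e-3, 1e-2) fixed. The component indicator is
// drawn from its marginalized conditional (effect integrated out), then
// the effect from its conditional normal. Uses R's RNG so set.seed()
// controls reproducibility.
//
// Residual vector is updated by single-site downdates and recomputed in
// full every `refresh_every` iterations to cap floating-point drift.

static inline double dot(const double* a, const double* b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// [[Rcpp::export]]
List bayesr_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix Z,
                      int n_iter, int n_burnin,
                      NumericVector gamma, NumericVector alpha,
                      double nu_g, double s2_g,
                      double sigma_g2_init, double sigma_e2_init,
                      NumericVector pi_init,
                      bool fix_pi, bool fix_sigma_g, bool fix_sigma_e,
                      int refresh_every) {
  const int n = y.size();
  const int m = Z.ncol();
  const int q = X.ncol();
  const int K = gamma.size();

  std::vector<double> b(q, 0.0), g(m, 0.0), zz(m), xx(q), pi(K), e(n);
  std::vector<int> comp(m, 0);
  for (int j = 0; j < m; ++j) zz[j] = dot(&Z(0, j), &Z(0, j), n);
  for (int l = 0; l < q; ++l) xx[l] = dot(&X(0, l), &X(0, l), n);
  for (int k = 0; k < K; ++k) pi[k] = pi_init[k];
  for (int i = 0; i < n; ++i) e[i] = y[i];

  double sg2 = sigma_g2_init, se2 = sigma_e2_init;
  const double vary = se2 + sg2;  // order-of-magnitude floor reference

  // accumulators (post burn-in)
  std::vector<double> g_sum(m, 0.0), b_sum(q, 0.0), pi_sum(K, 0.0);
  NumericMatrix comp_prob(m, K);
  double sg_sum = 0.0, se_sum = 0.0;
  int kept = 0;

  NumericVector sg_trace(n_iter), se_trace(n_iter);
  NumericMatrix pi_trace(n_iter, K);

  std::vector<double> logw(K), w(K);

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int l = 0; l < q; ++l) {
      const double* x = &X(0, l);
      double rhs = dot(x, &e[0], n) + xx[l] * b[l];
      double bn = R::rnorm(rhs / xx[l], std::sqrt(se2 / xx[l]));
      double diff = bn - b[l];
      for (int i = 0; i < n; ++i) e[i] -= x[i] * diff;
      b[l] = bn;
    }

    // SNP effects: marginalized component draw, then conditional normal
    for (int j = 0; j < m; ++j) {
      const double* z = &Z(0, j);
      double rhs = dot(z, &e[0], n) + zz[j] * g[j];
      double lmax = -DBL_MAX;
      for (int k = 0; k < K; ++k) {
        if (pi[k] <= 0.0) { logw[k] = -DBL_MAX; continue; }
        double v = gamma[k] * sg2;
        if (v <= 0.0) {
          logw[k] = std::log(pi[k]);
        } else {
          double denom = zz[j] * v + se2;
          logw[k] = std::log(pi[k]) - 0.5 * std::log(zz[j] * v / se2 + 1.0)
                    + 0.5 * rhs * rhs * v / (se2 * denom);
        }
        if (logw[k] > lmax) lmax = logw[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = (logw[k] <= -DBL_MAX) ? 0.0 : std::exp(logw[k] - lmax);
        tot += w[k];
      }
      double u = unif_rand() * tot, cum = 0.0;
      int knew = 0;
      for (int k = 0; k < K; ++k) { cum += w[k]; if (u <= cum) { knew = k; break; } }
      double gnew = 0.0;
      double v = gamma[knew] * sg2;
      if (v > 0.0) {
        double c = zz[j] + se2 / v;
        gnew = R::rnorm(rhs / c, std::sqrt(se2 / c));
      }
      double diff = gnew - g[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= z[i] * diff;
      g[j] = gnew;
      comp[j] = knew;
    }

    // mixture proportions: Dirichlet(alpha + counts)
    if (!fix_pi) {
      double tot = 0.0;
      std::vector<int> cnt(K, 0);
      for (int j = 0; j < m; ++j) cnt[comp[j]]++;
      for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(alpha[k] + cnt[k], 1.0); tot += pi[k]; }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }

    // genetic variance: scaled inverse chi-square conditional on effects
    if (!fix_sigma_g) {
      double ss = 0.0; int nnz = 0;
      for (int j = 0; j < m; ++j) {
        if (gamma[comp[j]] > 0.0) { ss += g[j] * g[j] / gamma[comp[j]]; nnz++; }
      }
      double df = nu_g + nnz;
      sg2 = (ss + nu_g * s2_g) / R::rchisq(df);
    }

    // residual variance: flat scaled inverse chi-square (nu = -2, S = 0)
    if (!fix_sigma_e) {
      double sse = dot(&e[0], &e[0], n);
      se2 = sse / R::rchisq((double)(n - 2));
      if (se2 < 1e-12 * vary) se2 = 1e-12 * vary;
    }

    if (!R_finite(se2) || !R_finite(sg2))
      stop("non-finite variance at iteration %d", it + 1);

    // periodic full residual recomputation
    if (refresh_every > 0 && (it + 1) % refresh_every == 0) {
      for (int i = 0; i < n; ++i) {
        double fit = 0.0;
        for (int l = 0; l < q; ++l) fit += X(i, l) * b[l];
        e[i] = y[i] - fit;
      }
      for (int j = 0; j < m; ++j) {
        if (g[j] != 0.0) {
          const double* z = &Z(0, j);
          for (int i = 0; i < n; ++i) e[i] -= z[i] * g[j];
        }
      }
    }

    sg_trace[it] = sg2;
    se_trace[it] = se2;
    for (int k = 0; k < K; ++k) pi_trace(it, k) = pi[k];

    if (it >= n_burnin) {
      kept++;
      for (int j = 0; j < m; ++j) { g_sum[j] += g[j]; comp_prob(j, comp[j]) += 1.0; }
      for (int l = 0; l < q; ++l) b_sum[l] += b[l];
      for (int k = 0; k < K; ++k) pi_sum[k] += pi[k];
      sg_sum += sg2;
      se_sum += se2;
    }
  }

  NumericVector gm(m), bm(q), pm(K);
  for (int j = 0; j < m; ++j) gm[j] = g_sum[j] / kept;
  for (int l = 0; l < q; ++l) bm[l] = b_sum[l] / kept;
  for (int k = 0; k < K; ++k) pm[k] = pi_sum[k] / kept;
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) comp_prob(j, k) /= kept;

  return List::create(
    _["effects"] = gm,
    _["fixed"] = bm,
    _["pi"] = pm,
    _["sigma_g2"] = sg_sum / kept,
    _["sigma_e2"] = se_sum / kept,
    _["comp_prob"] = comp_prob,
    _["sg_trace"] = sg_trace,
    _["se_trace"] = se_trace,
    _["pi_trace"] = pi_trace,
    _["n_kept"] = kept);
}
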