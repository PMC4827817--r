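// Gibbs sampler for the dynamic four-state occupancy model.
//
// Latent states are updated by forward-filtering backward-sampling over the
// 4-state chain; the initial state probabilities get a conjugate Dirichlet
// update; season-specific transition and detection effects get adaptive
// random-walk Metropolis updates against their complete-data multinomial
// likelihoods; hyper-means are conjugate normal; hyper-SDs are updated by
// random-walk Metropolis on the log scale.
//
// Indexing conventions (0-based internally):
//   transition effects  beta[t][m][k], t = 0..T-2, m = state 1..4, k = dest 2..4
//   detection effects   alpha[t][q][k], q = 0..5 over (m,n) pairs
//     q: 0=(2,2) 1=(3,2) 2=(3,3) 3=(4,2) 4=(4,3) 5=(4,4); k = (1, jd, jd^2)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int PAIR_M[6] = {1, 2, 2, 3, 3, 3};   // true state (0-based)
static const int PAIR_N[6] = {1, 1, 2, 1, 2, 3};   // observed state (0-based)
// pairs belonging to each true-state row (m = 1..3 zero-based => states 2..4)
static const int ROW_PAIRS[4][3] = {{-1,-1,-1}, {0,-1,-1}, {1,2,-1}, {3,4,5}};
static const int ROW_NPAIR[4] = {0, 1, 2, 3};

struct Dims {
  int I, T, nv;
};

// log Pr(y | true state m) for one visit given one season's detection row
static inline double ldet_entry(const std::vector<double>& alpha, int t,
                                int m /*0-based*/, int y /*0-based*/,
                                double x1, double x2, int Tq3 /*unused*/) {
  if (m == 0) return (y == 0) ? 0.0 : R_NegInf;
  if (y > m) return R_NegInf;
  int np = ROW_NPAIR[m];
  double eta[3], mx = 0.0;
  for (int j = 0; j < np; ++j) {
    int q = ROW_PAIRS[m][j];
    const double* a = &alpha[(size_t)(t * 6 + q) * 3];
    eta[j] = a[0] + a[1] * x1 + a[2] * x2;
    if (eta[j] > mx) mx = eta[j];
  }
  double den = std::exp(-mx);
  for (int j = 0; j < np; ++j) den += std::exp(eta[j] - mx);
  double lse = mx + std::log(den);
  if (y == 0) return -lse;
  for (int j = 0; j < np; ++j)
    if (PAIR_N[ROW_PAIRS[m][j]] == y) return eta[j] - lse;
  return R_NegInf;  // unreachable given constraints
}

// softmax row (baseline first) into p[4] from 3 effects
static inline void softmax_row(const double* b, double* p) {
  double mx = 0.0;
  for (int k = 0; k < 3; ++k) if (b[k] > mx) mx = b[k];
  double den = std::exp(-mx);
  for (int k = 0; k < 3; ++k) den += std::exp(b[k] - mx);
  p[0] = std::exp(-mx) / den;
  for (int k = 0; k < 3; ++k) p[k + 1] = std::exp(b[k] - mx) / den;
}

// multinomial loglik of one TPM row given counts over destinations
static inline double row_loglik(const double* b, const double* cnt) {
  double mx = 0.0;
  for (int k = 0; k < 3; ++k) if (b[k] > mx) mx = b[k];
  double den = std::exp(-mx);
  for (int k = 0; k < 3; ++k) den += std::exp(b[k] - mx);
  double lse = mx + std::log(den);
  double ll = -cnt[0] * lse;
  for (int k = 0; k < 3; ++k) ll += cnt[k + 1] * (b[k] - lse);
  // cnt[0] enters via baseline log p = -lse; others b - lse
  return ll;
}

// log prior density for a hyper-SD sigma, parameterized by ls = log(sigma);
// includes the change-of-variables Jacobian
static inline double lsd_prior(double ls, double shape, double rate,
                               bool on_variance) {
  double s = std::exp(ls);
  if (on_variance) {
    double v = s * s;
    return R::dgamma(v, shape, 1.0 / rate, 1) + std::log(2.0) + 2.0 * ls;
  }
  return R::dgamma(s, shape, 1.0 / rate, 1) + ls;
}

// [[Rcpp::export]]
List run_sampler_cpp(IntegerVector terr, IntegerVector seas, IntegerVector y,
                     NumericVector jd, int I, int T,
                     IntegerMatrix z_init,
                     int n_iter, int n_burn, int thin,
                     double mu_prior_sd, double sd_shape, double sd_rate,
                     bool sd_on_variance, NumericVector dir_conc,
                     bool keep_z) {
  const int nv = terr.size();
  const int Tm1 = T - 1;

  // visit index grouped by (territory, season) and by season
  std::vector<std::vector<int>> vis_it((size_t)I * T);
  std::vector<std::vector<int>> vis_t((size_t)T);
  for (int v = 0; v < nv; ++v) {
    vis_it[(size_t)terr[v] * T + seas[v]].push_back(v);
    vis_t[(size_t)seas[v]].push_back(v);
  }

  // state
  std::vector<double> phi0(4, 0.25);
  std::vector<double> beta((size_t)std::max(Tm1, 0) * 12, 0.0);
  std::vector<double> bmu(12, 0.0), bsig(12, 1.0);
  std::vector<double> alpha((size_t)T * 18, 0.0);
  std::vector<double> amu(18, 0.0), asig(18, 1.0);
  std::vector<int> z((size_t)I * T);
  for (int i = 0; i < I; ++i)
    for (int t = 0; t < T; ++t) z[(size_t)i * T + t] = z_init(i, t) - 1;

  // caches
  std::vector<double> tpm((size_t)std::max(Tm1, 0) * 16);  // linear scale
  auto refresh_tpm_row = [&](int t, int m) {
    softmax_row(&beta[(size_t)(t * 4 + m) * 3], &tpm[(size_t)t * 16 + m * 4]);
  };
  for (int t = 0; t < Tm1; ++t)
    for (int m = 0; m < 4; ++m) refresh_tpm_row(t, m);

  std::vector<double> ldet((size_t)nv * 4);  // [v][m]
  auto refresh_ldet_row = [&](int v, int m) {
    double x1 = jd[v], x2 = x1 * x1;
    ldet[(size_t)v * 4 + m] = ldet_entry(alpha, seas[v], m, y[v] - 1, x1, x2, 0);
  };
  for (int v = 0; v < nv; ++v)
    for (int m = 0; m < 4; ++m) refresh_ldet_row(v, m);

  // adaptive step sizes (log scale)
  std::vector<double> ls_beta((size_t)std::max(Tm1, 0) * 4, std::log(0.5));
  std::vector<double> ls_alpha((size_t)T * 6, std::log(0.5));
  std::vector<double> ls_bsig(12, std::log(0.5)), ls_asig(18, std::log(0.5));
  std::vector<int> acc_beta(ls_beta.size(), 0), try_beta(ls_beta.size(), 0);
  std::vector<int> acc_alpha(ls_alpha.size(), 0), try_alpha(ls_alpha.size(), 0);
  std::vector<int> acc_bsig(12, 0), try_bsig(12, 0);
  std::vector<int> acc_asig(18, 0), try_asig(18, 0);
  const int adapt_batch = 50;

  // output
  const int S = (n_iter - n_burn) / thin;
  NumericMatrix phi0_d(S, 4), bmu_d(S, 12), bsig_d(S, 12);
  NumericMatrix beta_d(S, std::max(Tm1, 0) * 12);
  NumericMatrix amu_d(S, 18), asig_d(S, 18), alpha_d(S, (size_t)T * 18);
  IntegerMatrix z_d(keep_z ? S : 1, keep_z ? I * T : 1);

  std::vector<double> fwd((size_t)T * 4), edet(4);
  std::vector<double> ctr((size_t)std::max(Tm1, 0) * 16);
  double n0[4];

  int s_out = 0;
  for (int it = 0; it < n_iter; ++it) {
    // ---- FFBS latent-state update --------------------------------------
    for (int i = 0; i < I; ++i) {
      for (int t = 0; t < T; ++t) {
        // per-season detection products (rescaled; constants cancel)
        double lmax = R_NegInf;
        double ld[4];
        for (int m = 0; m < 4; ++m) {
          double s = 0.0;
          for (int v : vis_it[(size_t)i * T + t]) s += ldet[(size_t)v * 4 + m];
          ld[m] = s;
          if (s > lmax) lmax = s;
        }
        if (!R_FINITE(lmax)) lmax = 0.0;
        for (int m = 0; m < 4; ++m)
          edet[m] = R_FINITE(ld[m]) ? std::exp(ld[m] - lmax) : 0.0;

        double tot = 0.0;
        if (t == 0) {
          for (int m = 0; m < 4; ++m) {
            fwd[m] = phi0[m] * edet[m];
            tot += fwd[m];
          }
        } else {
          const double* Phi = &tpm[(size_t)(t - 1) * 16];
          for (int n = 0; n < 4; ++n) {
            double s = 0.0;
            for (int m = 0; m < 4; ++m) s += fwd[(size_t)(t - 1) * 4 + m] * Phi[m * 4 + n];
            fwd[(size_t)t * 4 + n] = s * edet[n];
            tot += fwd[(size_t)t * 4 + n];
          }
        }
        if (tot <= 0.0) stop("all latent-state paths impossible (territory %d)", i + 1);
        for (int m = 0; m < 4; ++m) fwd[(size_t)t * 4 + m] /= tot;
      }
      // backward sampling
      {
        double u = R::runif(0.0, 1.0), c = 0.0;
        int pick = 3;
        for (int m = 0; m < 4; ++m) {
          c += fwd[(size_t)(T - 1) * 4 + m];
          if (u <= c) { pick = m; break; }
        }
        z[(size_t)i * T + (T - 1)] = pick;
      }
      for (int t = T - 2; t >= 0; --t) {
        int znext = z[(size_t)i * T + t + 1];
        const double* Phi = &tpm[(size_t)t * 16];
        double w[4], tot = 0.0;
        for (int m = 0; m < 4; ++m) {
          w[m] = fwd[(size_t)t * 4 + m] * Phi[m * 4 + znext];
          tot += w[m];
        }
        double u = R::runif(0.0, 1.0) * tot, c = 0.0;
        int pick = 3;
        for (int m = 0; m < 4; ++m) {
          c += w[m];
          if (u <= c) { pick = m; break; }
        }
        z[(size_t)i * T + t] = pick;
      }
    }

    // ---- sufficient statistics from z ----------------------------------
    for (int m = 0; m < 4; ++m) n0[m] = 0.0;
    for (int i = 0; i < I; ++i) n0[z[(size_t)i * T]] += 1.0;
    std::fill(ctr.begin(), ctr.end(), 0.0);
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < Tm1; ++t)
        ctr[(size_t)t * 16 + z[(size_t)i * T + t] * 4 + z[(size_t)i * T + t + 1]] += 1.0;

    // ---- phi0 | z : conjugate Dirichlet --------------------------------
    {
      double g[4], tot = 0.0;
      for (int m = 0; m < 4; ++m) {
        g[m] = R::rgamma(dir_conc[m] + n0[m], 1.0);
        tot += g[m];
      }
      for (int m = 0; m < 4; ++m) phi0[m] = g[m] / tot;
    }

    // ---- transition effects: RW Metropolis per (t, m) row ---------------
    for (int t = 0; t < Tm1; ++t) {
      for (int m = 0; m < 4; ++m) {
        double* b = &beta[(size_t)(t * 4 + m) * 3];
        const double* cnt = &ctr[(size_t)t * 16 + m * 4];
        double step = std::exp(ls_beta[(size_t)t * 4 + m]);
        double prop[3], lp_cur = row_loglik(b, cnt), lp_prop;
        double pr_cur = 0.0, pr_prop = 0.0;
        for (int k = 0; k < 3; ++k) {
          prop[k] = b[k] + step * R::norm_rand();
          pr_cur += R::dnorm(b[k], bmu[m * 3 + k], bsig[m * 3 + k], 1);
          pr_prop += R::dnorm(prop[k], bmu[m * 3 + k], bsig[m * 3 + k], 1);
        }
        lp_prop = row_loglik(prop, cnt);
        try_beta[(size_t)t * 4 + m]++;
        if (std::log(R::unif_rand()) < lp_prop + pr_prop - lp_cur - pr_cur) {
          for (int k = 0; k < 3; ++k) b[k] = prop[k];
          refresh_tpm_row(t, m);
          acc_beta[(size_t)t * 4 + m]++;
        }
      }
    }

    // ---- transition hyper-parameters ------------------------------------
    for (int m = 0; m < 4; ++m) {
      for (int k = 0; k < 3; ++k) {
        int h = m * 3 + k;
        // conjugate normal for the mean
        double sig2 = bsig[h] * bsig[h];
        double prec = Tm1 / sig2 + 1.0 / (mu_prior_sd * mu_prior_sd);
        double sum = 0.0;
        for (int t = 0; t < Tm1; ++t) sum += beta[(size_t)(t * 4 + m) * 3 + k];
        double mean = (sum / sig2) / prec;
        bmu[h] = mean + R::norm_rand() / std::sqrt(prec);
        // log-scale RW for the SD
        double ls_cur = std::log(bsig[h]);
        double ls_prop = ls_cur + std::exp(ls_bsig[h]) * R::norm_rand();
        double s_prop = std::exp(ls_prop);
        double ll_cur = lsd_prior(ls_cur, sd_shape, sd_rate, sd_on_variance);
        double ll_prop = lsd_prior(ls_prop, sd_shape, sd_rate, sd_on_variance);
        for (int t = 0; t < Tm1; ++t) {
          double e = beta[(size_t)(t * 4 + m) * 3 + k];
          ll_cur += R::dnorm(e, bmu[h], bsig[h], 1);
          ll_prop += R::dnorm(e, bmu[h], s_prop, 1);
        }
        try_bsig[h]++;
        if (std::log(R::unif_rand()) < ll_prop - ll_cur) {
          bsig[h] = s_prop;
          acc_bsig[h]++;
        }
      }
    }

    // ---- detection effects: RW Metropolis per (t, pair) -----------------
    for (int t = 0; t < T; ++t) {
      for (int q = 0; q < 6; ++q) {
        int m = PAIR_M[q];  // true-state row (0-based)
        double* a = &alpha[(size_t)(t * 6 + q) * 3];
        double cur[3] = {a[0], a[1], a[2]};
        double step = std::exp(ls_alpha[(size_t)t * 6 + q]);
        double prop[3];
        double pr_cur = 0.0, pr_prop = 0.0;
        for (int k = 0; k < 3; ++k) {
          prop[k] = cur[k] + step * R::norm_rand();
          pr_cur += R::dnorm(cur[k], amu[q * 3 + k], asig[q * 3 + k], 1);
          pr_prop += R::dnorm(prop[k], amu[q * 3 + k], asig[q * 3 + k], 1);
        }
        // complete-data likelihood over season-t visits at territories in
        // true state m (only row m of the DPM involves this pair)
        double ll_cur = 0.0, ll_prop = 0.0;
        for (int v : vis_t[(size_t)t]) {
          if (z[(size_t)terr[v] * T + t] != m) continue;
          ll_cur += ldet[(size_t)v * 4 + m];
        }
        for (int k = 0; k < 3; ++k) a[k] = prop[k];
        for (int v : vis_t[(size_t)t]) {
          if (z[(size_t)terr[v] * T + t] != m) continue;
          double x1 = jd[v];
          ll_prop += ldet_entry(alpha, t, m, y[v] - 1, x1, x1 * x1, 0);
        }
        try_alpha[(size_t)t * 6 + q]++;
        if (std::log(R::unif_rand()) < ll_prop + pr_prop - ll_cur - pr_cur) {
          acc_alpha[(size_t)t * 6 + q]++;
          for (int v : vis_t[(size_t)t]) refresh_ldet_row(v, m);
        } else {
          for (int k = 0; k < 3; ++k) a[k] = cur[k];
        }
      }
    }

    // ---- detection hyper-parameters -------------------------------------
    for (int q = 0; q < 6; ++q) {
      for (int k = 0; k < 3; ++k) {
        int h = q * 3 + k;
        double sig2 = asig[h] * asig[h];
        double prec = T / sig2 + 1.0 / (mu_prior_sd * mu_prior_sd);
        double sum = 0.0;
        for (int t = 0; t < T; ++t) sum += alpha[(size_t)(t * 6 + q) * 3 + k];
        double mean = (sum / sig2) / prec;
        amu[h] = mean + R::norm_rand() / std::sqrt(prec);

        double ls_cur = std::log(asig[h]);
        double ls_prop = ls_cur + std::exp(ls_asig[h]) * R::norm_rand();
        double s_prop = std::exp(ls_prop);
        double ll_cur = lsd_prior(ls_cur, sd_shape, sd_rate, sd_on_variance);
        double ll_prop = lsd_prior(ls_prop, sd_shape, sd_rate, sd_on_variance);
        for (int t = 0; t < T; ++t) {
          double e = alpha[(size_t)(t * 6 + q) * 3 + k];
          ll_cur += R::dnorm(e, amu[h], asig[h], 1);
          ll_prop += R::dnorm(e, amu[h], s_prop, 1);
        }
        try_asig[h]++;
        if (std::log(R::unif_rand()) < ll_prop - ll_cur) {
          asig[h] = s_prop;
          acc_asig[h]++;
        }
      }
    }

    // ---- adaptation (burn-in only) --------------------------------------
    if (it < n_burn && (it + 1) % adapt_batch == 0) {
      double gain = std::min(0.5, 5.0 / std::sqrt((it + 1.0) / adapt_batch));
      auto adapt = [&](std::vector<double>& ls, std::vector<int>& acc,
                       std::vector<int>& tries, double target) {
        for (size_t j = 0; j < ls.size(); ++j) {
          if (tries[j] == 0) continue;
          double rate = (double)acc[j] / tries[j];
          ls[j] += gain * (rate - target);
          acc[j] = 0;
          tries[j] = 0;
        }
      };
      adapt(ls_beta, acc_beta, try_beta, 0.30);
      adapt(ls_alpha, acc_alpha, try_alpha, 0.30);
      adapt(ls_bsig, acc_bsig, try_bsig, 0.44);
      adapt(ls_asig, acc_asig, try_asig, 0.44);
    }

    // ---- retain ----------------------------------------------------------
    if (it >= n_burn && (it - n_burn) % thin == 0 && s_out < S) {
      for (int m = 0; m < 4; ++m) phi0_d(s_out, m) = phi0[m];
      for (int h = 0; h < 12; ++h) { bmu_d(s_out, h) = bmu[h]; bsig_d(s_out, h) = bsig[h]; }
      for (size_t j = 0; j < beta.size(); ++j) beta_d(s_out, j) = beta[j];
      for (int h = 0; h < 18; ++h) { amu_d(s_out, h) = amu[h]; asig_d(s_out, h) = asig[h]; }
      for (size_t j = 0; j < alpha.size(); ++j) alpha_d(s_out, j) = alpha[j];
      if (keep_z)
        for (int i = 0; i < I; ++i)
          for (int t = 0; t < T; ++t)
            z_d(s_out, i * T + t) = z[(size_t)i * T + t] + 1;
      ++s_out;
    }

    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  double acc_b = 0.0, acc_a = 0.0;
  // post-burn-in rates (counters reset at last adaptation batch)
  long tb = 0, ta = 0, ab = 0, aa = 0;
  for (size_t j = 0; j < try_beta.size(); ++j) { tb += try_beta[j]; ab += acc_beta[j]; }
  for (size_t j = 0; j < try_alpha.size(); ++j) { ta += try_alpha[j]; aa += acc_alpha[j]; }
  acc_b = tb ? (double)ab / tb : NA_REAL;
  acc_a = ta ? (double)aa / ta : NA_REAL;

  return List::create(
    _["phi0"] = phi0_d, _["beta"] = beta_d, _["beta_mu"] = bmu_d,
    _["beta_sigma"] = bsig_d, _["alpha"] = alpha_d, _["alpha_mu"] = amu_d,
    _["alpha_sigma"] = asig_d, _["z"] = z_d,
    _["accept_beta"] = acc_b, _["accept_alpha"] = acc_a);
}

// One exact conditional draw of a latent state path by FFBS, for fixed
// parameters. `ltpm` is a (T-1) x 16 matrix of transition probabilities
// (row-major 4x4 per season, linear scale); `logdet` is T x 4 with the
// summed per-season log detection products. Returns the sampled path and
// the marginal log-likelihood (log of the forward normalizing constants).
// [[Rcpp::export]]
List ffbs_cpp(NumericVector phi0, NumericMatrix tpm_flat, NumericMatrix logdet) {
  int T = logdet.nrow();
  if (tpm_flat.nrow() != T - 1 || tpm_flat.ncol() != 16)
    stop("tpm_flat must be (T-1) x 16");
  std::vector<double> fwd((size_t)T * 4);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double lmax = R_NegInf, ed[4];
    for (int m = 0; m < 4; ++m) if (logdet(t, m) > lmax) lmax = logdet(t, m);
    if (!R_FINITE(lmax)) lmax = 0.0;
    for (int m = 0; m < 4; ++m)
      ed[m] = R_FINITE(logdet(t, m)) ? std::exp(logdet(t, m) - lmax) : 0.0;
    double tot = 0.0;
    for (int n = 0; n < 4; ++n) {
      double s;
      if (t == 0) {
        s = phi0[n];
      } else {
        s = 0.0;
        for (int m = 0; m < 4; ++m)
          s += fwd[(size_t)(t - 1) * 4 + m] * tpm_flat(t - 1, m * 4 + n);
      }
      fwd[(size_t)t * 4 + n] = s * ed[n];
      tot += fwd[(size_t)t * 4 + n];
    }
    if (tot <= 0.0) return List::create(_["z"] = IntegerVector(0), _["loglik"] = R_NegInf);
    ll += std::log(tot) + lmax;
    for (int n = 0; n < 4; ++n) fwd[(size_t)t * 4 + n] /= tot;
  }
  IntegerVector zout(T);
  {
    double u = R::unif_rand(), c = 0.0;
    int pick = 3;
    for (int m = 0; m < 4; ++m) { c += fwd[(size_t)(T - 1) * 4 + m]; if (u <= c) { pick = m; break; } }
    zout[T - 1] = pick + 1;
  }
  for (int t = T - 2; t >= 0; --t) {
    int zn = zout[t + 1] - 1;
    double w[4], tot = 0.0;
    for (int m = 0; m < 4; ++m) {
      w[m] = fwd[(size_t)t * 4 + m] * tpm_flat(t, m * 4 + zn);
      tot += w[m];
    }
    double u = R::unif_rand() * tot, c = 0.0;
    int pick = 3;
    for (int m = 0; m < 4; ++m) { c += w[m]; if (u <= c) { pick = m; break; } }
    zout[t] = pick + 1;
  }
  return List::create(_["z"] = zout, _["loglik"] = ll);
}
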