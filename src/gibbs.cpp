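// Single-chain Gibbs samplers for the weighted BLUP and four-component
// Bayesian mixture genomic prediction models:
//
//   y = 1*mu + M g + Z a + e,   e ~ N(0, D se2),  d_ii = 1/w_i
//   g_j ~ N(0, sg2)                      (BLUP)
//   g_j | c_j = k ~ N(0, s2_k),  P(c_j = k) = pi_k,  s2_1<=...<=s2_4  (mixture)
//   a ~ N(0, A sa2)
//   flat prior on mu; bounded-uniform priors on all variance components.
//
// Uses R's RNG throughout so chains are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// draw from (s2)^(-n/2) exp(-S/(2 s2)) truncated to [lb, ub];
// proper scaled-inverse-chi-square when n >= 3, else uniform on [lb, ub]
static double draw_var(double S, int n, double lb, double ub) {
  if (n >= 3 && S > 0.0) {
    for (int t = 0; t < 100; ++t) {
      double d = S / ::Rf_rchisq((double)(n - 2));
      if (d >= lb && d <= ub) return d;
    }
    double d = S / (double)(n - 2);      // conditional mode-scale fallback
    return std::min(std::max(d, lb), ub);
  }
  return ::Rf_runif(lb, ub);
}

// [[Rcpp::export]]
List gibbs_fit(const arma::vec& y, const arma::vec& w, const arma::mat& M,
               const arma::uvec& rec_animal, const arma::mat& Ainv,
               int n_cycles, int burn_in, int thin,
               bool mixture, const arma::vec& mix_props,
               bool update_variances,
               double sg2_init, const arma::vec& s2k_init,
               double sa2_init, double se2_init,
               double var_lower, double var_upper,
               bool keep_samples) {
  const int n = y.n_elem;
  const int p = M.n_cols;
  const int q = Ainv.n_rows;

  if ((int)rec_animal.n_elem != n) stop("rec_animal length mismatch");
  if ((int)M.n_rows != n) stop("design row mismatch");
  if (burn_in >= n_cycles) stop("config error: burn_in must be < n_cycles");

  // records grouped by animal (at most one per animal in typical use,
  // but repeated records are supported)
  std::vector< std::vector<int> > recs(q);
  for (int i = 0; i < n; ++i) {
    if (rec_animal[i] >= (unsigned)q) stop("rec_animal out of range");
    recs[rec_animal[i]].push_back(i);
  }

  arma::mat Mw = M.each_col() % w;             // n x p
  arma::vec mWm(p);
  for (int j = 0; j < p; ++j) mWm[j] = arma::dot(Mw.col(j), M.col(j));
  const double sum_w = arma::accu(w);

  // state
  double mu = arma::dot(w, y) / sum_w;
  arma::vec g(p, arma::fill::zeros);
  arma::vec a(q, arma::fill::zeros);
  double sg2 = sg2_init, sa2 = sa2_init, se2 = se2_init;
  arma::vec s2k = s2k_init;                    // mixture component variances
  arma::ivec comp(p);
  comp.fill(0);                                // start in first component
  arma::vec r = y - mu;                        // residual

  // accumulators (Welford)
  auto make0 = [](int k) { return arma::vec(k, arma::fill::zeros); };
  arma::vec m_g = make0(p), s_g = make0(p), m_a = make0(q), s_a = make0(q);
  double m_mu = 0, s_mu = 0;
  arma::vec m_var = make0(7), s_var = make0(7); // sg2, s2k(4), sa2, se2
  arma::mat comp_count(p, 4, arma::fill::zeros);
  long n_saved = 0, n_order_reject = 0;

  const int n_keep = keep_samples ? (n_cycles - burn_in) / thin : 0;
  arma::vec samp_mu(n_keep);
  arma::mat samp_g(n_keep, keep_samples ? p : 0);
  arma::mat samp_a(n_keep, keep_samples ? q : 0);
  arma::mat samp_var(n_keep, keep_samples ? 7 : 0);

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // --- mu ---
    r += mu;
    {
      double mean = arma::dot(w, r) / sum_w;
      mu = mean + ::norm_rand() * std::sqrt(se2 / sum_w);
    }
    r -= mu;

    // --- g, column-wise in fixed map order ---
    for (int j = 0; j < p; ++j) {
      double prior_var = mixture ? s2k[comp[j]] : sg2;
      double gold = g[j];
      if (prior_var <= 0) prior_var = var_lower;
      double rhs = arma::dot(Mw.col(j), r) + mWm[j] * gold;
      double prec = mWm[j] + se2 / prior_var;
      double mean = rhs / prec;
      double gnew = mean + ::norm_rand() * std::sqrt(se2 / prec);
      g[j] = gnew;
      if (gold != gnew) r += M.col(j) * (gold - gnew);
    }

    // --- mixture component indicators ---
    if (mixture && p > 0) {
      for (int j = 0; j < p; ++j) {
        double lp[4], lpmax = -1e308;
        for (int k = 0; k < 4; ++k) {
          if (mix_props[k] <= 0.0) { lp[k] = -1e308; continue; }
          double v = std::max(s2k[k], var_lower);
          lp[k] = std::log(mix_props[k]) - 0.5 * std::log(v)
                  - 0.5 * g[j] * g[j] / v;
          if (lp[k] > lpmax) lpmax = lp[k];
        }
        double cum[4], tot = 0;
        for (int k = 0; k < 4; ++k) {
          tot += (lp[k] > -1e307) ? std::exp(lp[k] - lpmax) : 0.0;
          cum[k] = tot;
        }
        double u = ::unif_rand() * tot;
        int knew = 3;
        for (int k = 0; k < 4; ++k) if (u <= cum[k]) { knew = k; break; }
        comp[j] = knew;
      }
    }

    // --- a, animal-wise single-site ---
    for (int t = 0; t < q; ++t) {
      double at = a[t];
      double prec = Ainv(t, t) / sa2;
      double rhs = -(arma::dot(Ainv.col(t), a) - Ainv(t, t) * at) / sa2;
      for (size_t k = 0; k < recs[t].size(); ++k) {
        int i = recs[t][k];
        prec += w[i] / se2;
        rhs += w[i] * (r[i] + at) / se2;
      }
      double anew = rhs / prec + ::norm_rand() / std::sqrt(prec);
      a[t] = anew;
      if (anew != at)
        for (size_t k = 0; k < recs[t].size(); ++k)
          r[recs[t][k]] -= (anew - at);
    }

    // --- variance components ---
    if (update_variances) {
      if (mixture) {
        int nk[4] = {0, 0, 0, 0};
        double Sk[4] = {0, 0, 0, 0};
        for (int j = 0; j < p; ++j) {
          nk[comp[j]]++;
          Sk[comp[j]] += g[j] * g[j];
        }
        bool ok = false;
        arma::vec prop(4);
        for (int t = 0; t < 100 && !ok; ++t) {
          for (int k = 0; k < 4; ++k)
            prop[k] = draw_var(Sk[k], nk[k], var_lower, var_upper);
          ok = prop.is_sorted("ascend");
          if (!ok) ++n_order_reject;
        }
        if (ok) s2k = prop;
      } else if (p > 0) {
        sg2 = draw_var(arma::dot(g, g), p, var_lower, var_upper);
      }
      double qf = arma::as_scalar(a.t() * Ainv * a);
      sa2 = draw_var(qf, q, var_lower, var_upper);
      double ssr = arma::dot(w, r % r);
      se2 = draw_var(ssr, n, var_lower, var_upper);
    }

    // --- accumulate ---
    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      ++n_saved;
      double dmu = mu - m_mu;
      m_mu += dmu / n_saved; s_mu += dmu * (mu - m_mu);
      for (int j = 0; j < p; ++j) {
        double d = g[j] - m_g[j];
        m_g[j] += d / n_saved; s_g[j] += d * (g[j] - m_g[j]);
        comp_count(j, comp[j]) += 1.0;
      }
      for (int t = 0; t < q; ++t) {
        double d = a[t] - m_a[t];
        m_a[t] += d / n_saved; s_a[t] += d * (a[t] - m_a[t]);
      }
      arma::vec vv = {sg2, s2k[0], s2k[1], s2k[2], s2k[3], sa2, se2};
      for (int k = 0; k < 7; ++k) {
        double d = vv[k] - m_var[k];
        m_var[k] += d / n_saved; s_var[k] += d * (vv[k] - m_var[k]);
      }
      if (keep_samples) {
        int row = n_saved - 1;
        samp_mu[row] = mu;
        samp_g.row(row) = g.t();
        samp_a.row(row) = a.t();
        samp_var.row(row) = vv.t();
      }
    }
    if (cyc % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  auto sdify = [&](arma::vec& s) {
    arma::vec out = s;
    if (n_saved > 1) out = arma::sqrt(s / (n_saved - 1));
    else out.zeros();
    return out;
  };
  List out = List::create(
    _["mu_mean"] = m_mu,
    _["mu_sd"] = (n_saved > 1) ? std::sqrt(s_mu / (n_saved - 1)) : 0.0,
    _["g_mean"] = m_g, _["g_sd"] = sdify(s_g),
    _["a_mean"] = m_a, _["a_sd"] = sdify(s_a),
    _["var_mean"] = m_var, _["var_sd"] = sdify(s_var),
    _["comp_freq"] = comp_count / std::max(1.0, (double)n_saved),
    _["n_saved"] = (double)n_saved,
    _["n_order_reject"] = (double)n_order_reject);
  if (keep_samples)
    out["samples"] = List::create(_["mu"] = samp_mu, _["g"] = samp_g,
                                  _["a"] = samp_a, _["var"] = samp_var);
  return out;
}
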