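// Local-level (random-walk plus noise) state-space model:
//   w(t)  ~ N(mu(t),  sigma_obs)
//   mu(t) ~ N(mu(t-1), sigma_mu)
//   mu(1) ~ N(m1, p1_sd)
// Kalman filtering, forward-filtering backward-sampling (FFBS), and a
// hierarchical Gibbs/Metropolis sampler in which per-participant noise SDs
// are drawn from truncated-normal group distributions.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double dnorm_log(double x, double mean, double sd) {
  double z = (x - mean) / sd;
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) - 0.5 * z * z;
}

// log density of N(mean, sd) truncated to [lo, hi], evaluated at x
static double dtnorm_log(double x, double mean, double sd, double lo, double hi) {
  if (x < lo || x > hi || sd <= 0.0) return R_NegInf;
  double z  = R::pnorm(hi, mean, sd, 1, 0) - R::pnorm(lo, mean, sd, 1, 0);
  if (z <= 0.0) return R_NegInf;
  return dnorm_log(x, mean, sd) - std::log(z);
}

// [[Rcpp::export]]
double kalman_loglik_cpp(const arma::vec& w, double sigma_obs, double sigma_mu,
                         double m1, double p1_sd) {
  const int T = w.n_elem;
  const double vo = sigma_obs * sigma_obs, vm = sigma_mu * sigma_mu;
  double m = m1, P = p1_sd * p1_sd, ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) P += vm;
    const double F = P + vo;
    const double v = w[t] - m;
    ll += -0.5 * (std::log(2.0 * M_PI * F) + v * v / F);
    const double K = P / F;
    m += K * v;
    P *= (1.0 - K);
  }
  return ll;
}

// Draw one latent path mu | w, sigma_obs, sigma_mu (FFBS).
// Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::vec ffbs_local_level_cpp(const arma::vec& w, double sigma_obs,
                               double sigma_mu, double m1, double p1_sd) {
  const int T = w.n_elem;
  const double vo = sigma_obs * sigma_obs;
  const double vm = std::max(sigma_mu * sigma_mu, 1e-14);
  arma::vec mf(T), Pf(T);
  double m = m1, P = p1_sd * p1_sd;
  for (int t = 0; t < T; ++t) {
    if (t > 0) P += vm;
    const double F = P + vo;
    const double K = P / F;
    m += K * (w[t] - m);
    P *= (1.0 - K);
    mf[t] = m;
    Pf[t] = std::max(P, 1e-14);
  }
  arma::vec mu(T);
  mu[T - 1] = mf[T - 1] + std::sqrt(Pf[T - 1]) * R::norm_rand();
  for (int t = T - 2; t >= 0; --t) {
    const double Pp = Pf[t] + vm;           // Var(mu_{t+1} | w_{1:t})
    const double J  = Pf[t] / Pp;
    const double cm = mf[t] + J * (mu[t + 1] - mf[t]);
    const double cv = std::max(Pf[t] * (1.0 - J), 1e-14);
    mu[t] = cm + std::sqrt(cv) * R::norm_rand();
  }
  return mu;
}

// Random-walk Metropolis step on log(sigma).
// loglik_fn is evaluated inline by callers; here we pass precomputed pieces.
struct MHResult { double value; bool accepted; };

static MHResult mh_sigma(double cur, double prop_sd, double ub,
                         const std::function<double(double)>& logpost) {
  const double lcur = logpost(cur);
  const double prop = cur * std::exp(prop_sd * R::norm_rand());
  MHResult out{cur, false};
  if (prop > 0.0 && prop <= ub) {
    const double lprop = logpost(prop);
    // Jacobian of the log-scale random walk: + log(prop) - log(cur)
    const double lacc = lprop - lcur + std::log(prop) - std::log(cur);
    if (std::log(R::unif_rand()) < lacc) { out.value = prop; out.accepted = true; }
  }
  return out;
}

// Hierarchical Gibbs sampler for a set of weight series in one phase.
// w_list: list of numeric vectors (one per participant).
// Returns kept draws of per-participant SDs and group hyperparameters, plus
// accumulated posterior means/SDs of the latent paths.
// [[Rcpp::export]]
List mcmc_local_level_cpp(const List& w_list,
                          int n_iter, int burn, int thin,
                          double sd_ub, double mean_lb, double mean_ub,
                          double p1_sd, bool hierarchical,
                          double prop_sd,
                          const arma::vec& init_sigma_obs,
                          const arma::vec& init_sigma_mu,
                          double init_gmu_obs, double init_gsd_obs,
                          double init_gmu_mu, double init_gsd_mu) {
  const int n = w_list.size();
  std::vector<arma::vec> w(n);
  for (int i = 0; i < n; ++i) w[i] = as<arma::vec>(w_list[i]);

  arma::vec s_obs = init_sigma_obs, s_mu = init_sigma_mu;
  double gmu_obs = init_gmu_obs, gsd_obs = init_gsd_obs;
  double gmu_mu = init_gmu_mu, gsd_mu = init_gsd_mu;

  std::vector<arma::vec> mu(n);
  for (int i = 0; i < n; ++i) mu[i] = w[i];

  const int n_keep = (n_iter - burn) / thin;
  arma::mat keep_obs(n_keep, n), keep_mu(n_keep, n);
  arma::mat keep_group(n_keep, 4);
  std::vector<arma::vec> path_sum(n), path_sumsq(n);
  for (int i = 0; i < n; ++i) {
    path_sum[i] = arma::zeros(w[i].n_elem);
    path_sumsq[i] = arma::zeros(w[i].n_elem);
  }

  auto prior_sd = [&](double s, double gmu, double gsd) {
    if (hierarchical) return dtnorm_log(s, gmu, gsd, 0.0, sd_ub);
    return (s > 0.0 && s <= sd_ub) ? -std::log(sd_ub) : R_NegInf;
  };

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // 1. per-participant SDs via marginal (path-integrated) Kalman
    //    likelihood — decouples the SDs from the latent path draw
    for (int i = 0; i < n; ++i) {
      auto lp_obs = [&](double s) {
        double ll = prior_sd(s, gmu_obs, gsd_obs);
        if (!std::isfinite(ll)) return ll;
        return ll + kalman_loglik_cpp(w[i], s, s_mu[i], w[i][0], p1_sd);
      };
      s_obs[i] = mh_sigma(s_obs[i], prop_sd, sd_ub, lp_obs).value;

      auto lp_mu = [&](double s) {
        double ll = prior_sd(s, gmu_mu, gsd_mu);
        if (!std::isfinite(ll)) return ll;
        return ll + kalman_loglik_cpp(w[i], s_obs[i], s, w[i][0], p1_sd);
      };
      s_mu[i] = mh_sigma(s_mu[i], prop_sd, sd_ub, lp_mu).value;
    }

    // 2. group hyperparameters (only meaningful with >= 2 participants)
    if (hierarchical) {
      auto group_ll = [&](const arma::vec& s, double gmu, double gsd) {
        double ll = 0.0;
        for (int i = 0; i < n; ++i) ll += dtnorm_log(s[i], gmu, gsd, 0.0, sd_ub);
        return ll;
      };
      // means: random-walk MH on a uniform [mean_lb, mean_ub] prior
      {
        double prop = gmu_obs + 0.05 * R::norm_rand();
        if (prop >= mean_lb && prop <= mean_ub) {
          double lacc = group_ll(s_obs, prop, gsd_obs) - group_ll(s_obs, gmu_obs, gsd_obs);
          if (std::log(R::unif_rand()) < lacc) gmu_obs = prop;
        }
        prop = gmu_mu + 0.05 * R::norm_rand();
        if (prop >= mean_lb && prop <= mean_ub) {
          double lacc = group_ll(s_mu, prop, gsd_mu) - group_ll(s_mu, gmu_mu, gsd_mu);
          if (std::log(R::unif_rand()) < lacc) gmu_mu = prop;
        }
      }
      // scales: log random walk on a uniform (0, sd_ub] prior
      {
        auto lp_gsd_obs = [&](double g) { return group_ll(s_obs, gmu_obs, g); };
        gsd_obs = mh_sigma(gsd_obs, prop_sd, sd_ub, lp_gsd_obs).value;
        auto lp_gsd_mu = [&](double g) { return group_ll(s_mu, gmu_mu, g); };
        gsd_mu = mh_sigma(gsd_mu, prop_sd, sd_ub, lp_gsd_mu).value;
      }
    }

    if (it >= burn && ((it - burn) % thin == 0) && kept < n_keep) {
      for (int i = 0; i < n; ++i) {
        // latent path draw (FFBS) needed only when recording
        mu[i] = ffbs_local_level_cpp(w[i], s_obs[i], s_mu[i], w[i][0], p1_sd);
        keep_obs(kept, i) = s_obs[i];
        keep_mu(kept, i) = s_mu[i];
        path_sum[i] += mu[i];
        path_sumsq[i] += arma::square(mu[i]);
      }
      keep_group(kept, 0) = gmu_obs;
      keep_group(kept, 1) = gsd_obs;
      keep_group(kept, 2) = gmu_mu;
      keep_group(kept, 3) = gsd_mu;
      ++kept;
    }
  }

  List path_mean(n), path_sd(n);
  for (int i = 0; i < n; ++i) {
    arma::vec pm = path_sum[i] / std::max(kept, 1);
    arma::vec pv = path_sumsq[i] / std::max(kept, 1) - arma::square(pm);
    pv.transform([](double v) { return std::sqrt(std::max(v, 0.0)); });
    path_mean[i] = pm;
    path_sd[i] = pv;
  }
  return List::create(_["sigma_obs"] = keep_obs,
                      _["sigma_mu"] = keep_mu,
                      _["group"] = keep_group,
                      _["path_mean"] = path_mean,
                      _["path_sd"] = path_sd);
}
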