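// Time-varying-coefficient decomposition of estimation during interaction:
//   Est(t) = (Baseline + Coef_Atyp(t) * Atyp(t-1) + Coef_Sim(t) * Sim(t-1))
//            * DotNum(t) + eps,   eps ~ N(0, sigma_eps)
// with local-linear-trend dynamics on each time-varying coefficient:
//   Coef(t)  ~ N(Coef(t-1) + gamma(t-1), sigma_Coef)
//   gamma(t) ~ N(gamma(t-1),             sigma_gamma)
// Baseline is static with prior N(w_pre, sigma_baseline).
// Reduced models drop components; a dropped Baseline is pinned at w_pre.
// Gibbs sampler: FFBS for the state vector, log-scale Metropolis for SDs.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double mh_logsd(double cur, double ub, double prop_sd,
                       const std::function<double(double)>& logpost) {
  const double lcur = logpost(cur);
  const double prop = cur * std::exp(prop_sd * R::norm_rand());
  if (prop <= 0.0 || prop > ub) return cur;
  const double lacc = logpost(prop) - lcur + std::log(prop) - std::log(cur);
  if (std::log(R::unif_rand()) < lacc) return prop;
  return cur;
}

static double gauss_ll(const arma::vec& res, double s) {
  const int m = res.n_elem;
  return -m * std::log(s) - 0.5 * arma::dot(res, res) / (s * s)
         - 0.5 * m * std::log(2.0 * M_PI);
}

// Draw from N(mean, Sigma) with a jittered Cholesky for near-singular Sigma.
static arma::vec mvn_draw(const arma::vec& mean, arma::mat Sigma) {
  const int d = mean.n_elem;
  Sigma = arma::symmatu(Sigma);
  arma::mat L;
  double jitter = 1e-12;
  while (!arma::chol(L, Sigma + jitter * arma::eye(d, d), "lower"))
    jitter *= 10.0;
  arma::vec z(d);
  for (int k = 0; k < d; ++k) z[k] = R::norm_rand();
  return mean + L * z;
}

// y: adjusted observations (length m, trials 2..T of the session)
// Z: m x d observation vectors (rows); Tmat: d x d transition;
// q_idx: for each state dim, index into the scale vector (or -1 for no noise)
// [[Rcpp::export]]
List mcmc_tvc_cpp(const arma::vec& y, const arma::mat& Z,
                  const arma::mat& Tmat, const arma::ivec& q_idx,
                  const arma::vec& a1, const arma::vec& p1_sd,
                  int n_scales, double scale_ub, double sigma_eps_ub,
                  int n_iter, int burn, int thin, double prop_sd,
                  const arma::vec& init_scales, double init_sigma_eps,
                  int coef_sim_dim) {
  const int m = y.n_elem;
  const int d = a1.n_elem;
  arma::vec scales = init_scales;          // n_scales trend/level SDs
  double s_eps = init_sigma_eps;

  arma::mat X(d, m, arma::fill::zeros);    // current state draw (d may be 0)
  const int n_keep = (n_iter - burn) / thin;
  arma::mat keep_scales(n_keep, std::max(n_scales, 1), arma::fill::zeros);
  arma::vec keep_eps(n_keep);
  arma::mat keep_ll(n_keep, m);
  arma::vec keep_mean_coef_sim(n_keep, arma::fill::zeros);
  arma::mat state_sum(d, m, arma::fill::zeros);

  // FFBS storage
  arma::mat mf(d, m), af(d, m);
  arma::cube Pf(d, d, m), Pp(d, d, m);

  auto build_Q = [&](void) {
    arma::mat Q(d, d, arma::fill::zeros);
    for (int k = 0; k < d; ++k)
      if (q_idx[k] >= 0) Q(k, k) = scales[q_idx[k]] * scales[q_idx[k]];
    return Q;
  };

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (d > 0) {
      // forward filter
      const arma::mat Q = build_Q();
      arma::vec a = a1;
      arma::mat P = arma::diagmat(arma::square(p1_sd));
      const double ve = s_eps * s_eps;
      for (int t = 0; t < m; ++t) {
        if (t > 0) {
          a = Tmat * mf.col(t - 1);
          P = Tmat * Pf.slice(t - 1) * Tmat.t() + Q;
        }
        af.col(t) = a;
        Pp.slice(t) = P;
        const arma::vec z = Z.row(t).t();
        const double F = arma::as_scalar(z.t() * P * z) + ve;
        const arma::vec K = P * z / F;
        mf.col(t) = a + K * (y[t] - arma::dot(z, a));
        Pf.slice(t) = arma::symmatu(P - K * z.t() * P);
      }
      // backward sample
      X.col(m - 1) = mvn_draw(mf.col(m - 1), Pf.slice(m - 1));
      for (int t = m - 2; t >= 0; --t) {
        const arma::mat Ppn = arma::symmatu(Pp.slice(t + 1)) +
                              1e-12 * arma::eye(d, d);
        const arma::mat J = Pf.slice(t) * Tmat.t() * arma::inv_sympd(Ppn);
        const arma::vec cm = mf.col(t) + J * (X.col(t + 1) - af.col(t + 1));
        const arma::mat cP = Pf.slice(t) - J * Pp.slice(t + 1) * J.t();
        X.col(t) = mvn_draw(cm, cP);
      }

      // scale updates: increments implied by the sampled states
      for (int s = 0; s < n_scales; ++s) {
        std::vector<double> inc;
        for (int k = 0; k < d; ++k) {
          if (q_idx[k] != s) continue;
          for (int t = 1; t < m; ++t)
            inc.push_back(X(k, t) - arma::dot(Tmat.row(k).t(), X.col(t - 1)));
        }
        if (inc.empty()) continue;
        const arma::vec v(inc);
        auto lp = [&](double sd) { return gauss_ll(v, sd); };
        scales[s] = mh_logsd(scales[s], scale_ub, prop_sd, lp);
      }
    }

    // observation noise
    arma::vec fitted(m);
    for (int t = 0; t < m; ++t)
      fitted[t] = (d > 0) ? arma::dot(Z.row(t).t(), X.col(t)) : 0.0;
    const arma::vec res = y - fitted;
    auto lp_eps = [&](double sd) { return gauss_ll(res, sd); };
    s_eps = mh_logsd(s_eps, sigma_eps_ub, prop_sd, lp_eps);

    if (it >= burn && ((it - burn) % thin == 0) && kept < n_keep) {
      for (int s = 0; s < n_scales; ++s) keep_scales(kept, s) = scales[s];
      keep_eps[kept] = s_eps;
      // pointwise log-likelihood for WAIC: one-step-ahead predictive
      // p(y_t | y_{1:t-1}, scales) with the states marginalized out by the
      // Kalman filter — conditional-on-states likelihoods make WAIC reward
      // state paths that chase noise
      if (d > 0) {
        const arma::mat Q = build_Q();
        arma::vec a = a1;
        arma::mat P = arma::diagmat(arma::square(p1_sd));
        const double ve = s_eps * s_eps;
        arma::vec mcur(d);
        for (int t = 0; t < m; ++t) {
          if (t > 0) {
            a = Tmat * mcur;
            P = Tmat * P * Tmat.t() + Q;
          }
          const arma::vec z = Z.row(t).t();
          const double F = arma::as_scalar(z.t() * P * z) + ve;
          const double v = y[t] - arma::dot(z, a);
          keep_ll(kept, t) = -0.5 * (std::log(2.0 * M_PI * F) + v * v / F);
          const arma::vec K = P * z / F;
          mcur = a + K * v;
          P = arma::symmatu(P - K * z.t() * P);
        }
      } else {
        for (int t = 0; t < m; ++t)
          keep_ll(kept, t) = R::dnorm(y[t], 0.0, s_eps, 1);
      }
      if (coef_sim_dim >= 0)
        keep_mean_coef_sim[kept] = arma::mean(X.row(coef_sim_dim));
      state_sum += X;
      ++kept;
    }
  }

  arma::mat state_mean = (kept > 0) ? arma::mat(state_sum / kept)
                                    : arma::mat(d, m, arma::fill::zeros);
  return List::create(_["scales"] = keep_scales,
                      _["sigma_eps"] = keep_eps,
                      _["loglik"] = keep_ll,
                      _["mean_coef_sim"] = keep_mean_coef_sim,
                      _["state_mean"] = state_mean);
}
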