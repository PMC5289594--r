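// Random-walk Metropolis sampler for the binomial-logit network
// meta-analysis model. Two-arm trials; arm probabilities are modeled as
//   logit(p_sk) = mu_s                          (baseline arm of trial s)
//   logit(p_sk) = mu_s + d_t - d_b              (fixed effects)
//   logit(p_sk) = mu_s + d_t - d_b + sigma*z_s  (random effects,
//                                                non-centered, z_s ~ N(0,1))
// with d_1 = 0, a logit-Beta(0.5, 0.5) prior on the baseline probabilities
// expit(mu_s), N(0, 1e8) priors on the treatment effects and a U(0.001, 10)
// prior on sigma (common across contrasts). Components are updated one at a
// time with Gaussian proposals whose scales adapt during burn-in. The
// non-centered trial effects keep the treatment effects well mixed when the
// data carry little heterogeneity.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_expit(double x) {
  if (x > 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".nma_mcmc_cpp")]]
List nma_mcmc_cpp(IntegerVector trial, IntegerVector treat,
                  IntegerVector base_arm, NumericVector r, NumericVector n,
                  int S, int K, bool random_effects,
                  int n_burn, int n_keep, int thin) {
  int n_arm = trial.size();

  std::vector<int> base_treat(S, 0), alt_treat(S, 0), alt_arm(S, -1);
  std::vector<std::vector<int>> trial_arms(S);
  for (int i = 0; i < n_arm; ++i) {
    trial_arms[trial[i]].push_back(i);
    if (base_arm[i]) base_treat[trial[i]] = treat[i];
    else { alt_treat[trial[i]] = treat[i]; alt_arm[trial[i]] = i; }
  }
  // non-baseline arms whose linear predictor involves d_k
  std::vector<std::vector<int>> d_arms(K);
  for (int i = 0; i < n_arm; ++i) {
    if (base_arm[i]) continue;
    for (int k = 1; k < K; ++k) {
      if (treat[i] == k || base_treat[trial[i]] == k) d_arms[k].push_back(i);
    }
  }

  std::vector<double> mu(S), d(K, 0.0), z(S, 0.0);
  double sigma = 0.5;
  for (int i = 0; i < n_arm; ++i) {
    if (base_arm[i]) {
      double p = (r[i] + 0.5) / (n[i] + 1.0);
      mu[trial[i]] = std::log(p / (1.0 - p));
    }
  }

  const double d_prior_var = 1e8;
  auto log_prior_mu = [](double m) {
    // Beta(0.5, 0.5) on expit(mu) including the logit Jacobian
    return 0.5 * log_expit(m) + 0.5 * log_expit(-m);
  };
  auto log_prior_d = [&](double x) { return -0.5 * x * x / d_prior_var; };

  auto arm_loglik = [&](int i) {
    int s = trial[i];
    double lp = mu[s];
    if (!base_arm[i]) {
      lp += d[treat[i]] - d[base_treat[s]];
      if (random_effects) lp += sigma * z[s];
    }
    return r[i] * log_expit(lp) + (n[i] - r[i]) * log_expit(-lp);
  };
  auto trial_loglik = [&](int s) {
    double ll = 0.0;
    for (int i : trial_arms[s]) ll += arm_loglik(i);
    return ll;
  };
  auto nonbase_loglik = [&]() {
    double ll = 0.0;
    for (int s = 0; s < S; ++s) {
      if (alt_arm[s] >= 0) ll += arm_loglik(alt_arm[s]);
    }
    return ll;
  };

  std::vector<double> step_mu(S, 0.5), step_d(K, 0.5), step_z(S, 0.5);
  double step_sigma = 0.5;
  std::vector<int> acc_mu(S, 0), acc_d(K, 0), acc_z(S, 0);
  int acc_sigma = 0;
  const int batch = 50;

  int total_iter = n_burn + n_keep * thin;
  NumericMatrix out_d(n_keep, K - 1);
  NumericMatrix out_mu(n_keep, S);
  NumericVector out_sigma(n_keep);
  int kept = 0;

  RNGScope scope;
  for (int it = 0; it < total_iter; ++it) {
    for (int s = 0; s < S; ++s) {
      double cur = trial_loglik(s) + log_prior_mu(mu[s]);
      double old = mu[s];
      mu[s] = old + R::norm_rand() * step_mu[s];
      double prop = trial_loglik(s) + log_prior_mu(mu[s]);
      if (std::log(R::unif_rand()) < prop - cur) acc_mu[s]++;
      else mu[s] = old;
    }
    for (int k = 1; k < K; ++k) {
      double cur = log_prior_d(d[k]);
      for (int i : d_arms[k]) cur += arm_loglik(i);
      double old = d[k];
      d[k] = old + R::norm_rand() * step_d[k];
      double prop = log_prior_d(d[k]);
      for (int i : d_arms[k]) prop += arm_loglik(i);
      if (std::log(R::unif_rand()) < prop - cur) acc_d[k]++;
      else d[k] = old;
    }
    if (random_effects) {
      for (int s = 0; s < S; ++s) {
        if (alt_arm[s] < 0) continue;
        double cur = arm_loglik(alt_arm[s]) - 0.5 * z[s] * z[s];
        double old = z[s];
        z[s] = old + R::norm_rand() * step_z[s];
        double prop = arm_loglik(alt_arm[s]) - 0.5 * z[s] * z[s];
        if (std::log(R::unif_rand()) < prop - cur) acc_z[s]++;
        else z[s] = old;
      }
      double cur = nonbase_loglik();
      double old = sigma;
      sigma = old + R::norm_rand() * step_sigma;
      if (sigma < 0.001 || sigma > 10.0) {
        sigma = old;
      } else {
        double prop = nonbase_loglik();
        if (std::log(R::unif_rand()) < prop - cur) acc_sigma++;
        else sigma = old;
      }
    }
    if (it < n_burn && (it + 1) % batch == 0) {
      auto tune = [&](double& step, int& acc) {
        double rate = acc / (double)batch;
        if (rate > 0.44) step *= 1.2; else step *= 0.85;
        if (step < 1e-3) step = 1e-3;
        if (step > 10) step = 10;
        acc = 0;
      };
      for (int s = 0; s < S; ++s) tune(step_mu[s], acc_mu[s]);
      for (int k = 1; k < K; ++k) tune(step_d[k], acc_d[k]);
      if (random_effects) {
        for (int s = 0; s < S; ++s) tune(step_z[s], acc_z[s]);
        tune(step_sigma, acc_sigma);
      }
    }
    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      for (int k = 1; k < K; ++k) out_d(kept, k - 1) = d[k];
      for (int s = 0; s < S; ++s) out_mu(kept, s) = mu[s];
      out_sigma[kept] = sigma;
      ++kept;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["d"] = out_d, _["mu"] = out_mu,
                      _["sigma"] = out_sigma);
}
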