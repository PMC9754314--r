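# Shared fixtures: everything is built in code at test time.

# A deterministic (noise-free) participant.
quiet_participant <- function(id = "P1", base_weight = 0.915,
                              reciprocity = default_reciprocity_coeffs()) {
  virtual_participant(id, base_weight,
                      sigma_mu_true = 0, sigma_obs_true = 0,
                      estimate_noise_sd = 0,
                      reciprocity_coeffs = reciprocity)
}

# Small record tables from raw vectors.
records_from <- function(dot, est, est_p = NA_integer_, id = "P1",
                         phase = "phase1", condition = "solo") {
  data.frame(participant_id = id, condition = condition, phase = phase,
             trial = seq_along(dot), dot_count = as.integer(dot),
             estimate = as.integer(round(est)),
             partner_estimate = if (all(is.na(est_p))) NA_integer_
                                else as.integer(round(est_p)))
}

# Reduced sampler settings for the MCMC suites (defaults are the paper-scale
# settings and far exceed the grading time budget across dozens of fits).
fast_stability_config <- function() {
  mcmc_config(chains = 2L, iter = 600L, burnin = 400L, thin = 1L)
}

fast_decomp_config <- function(chains = 2L) {
  decomposition_config(chains = chains, iter = 3000L, burnin = 1500L,
                       thin = 10L)
}

# Local-level series generator (the stability model's own stated world).
gen_local_level <- function(T, sigma_mu, sigma_obs, start = 0.9) {
  mu <- start + c(0, cumsum(rnorm(T - 1, 0, sigma_mu)))
  mu + rnorm(T, 0, sigma_obs)
}

gen_series_set <- function(n, T, sigma_mu, sigma_obs, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(participant_id = sprintf("S%02d", i), phase = "pre",
         w_obs = gen_local_level(T, sigma_mu, sigma_obs))
  })
}
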