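#' Atypicality regressor
#'
#' How far the partner's estimate on the preceding trial lay from what a
#' reference observer (weight `reference_weight`, default the behavioral
#' population mean 0.91) would say:
#' `Atyp = 1 - Est_p / (reference_weight * DotNum)`. Positive values mark a
#' partner estimating below the reference observer.
#'
#' @param partner_estimate partner estimate(s).
#' @param dot_count dot magnitude(s), > 0.
#' @param reference_weight reference estimation weight.
#' @return numeric atypicality value(s).
#' @export
compute_atyp <- function(partner_estimate, dot_count, reference_weight = 0.91) {
  if (any(dot_count <= 0)) stop("dot_count must be positive")
  1 - partner_estimate / (reference_weight * dot_count)
}

#' Similarity regressor
#'
#' Closeness of the two estimates relative to the pair's pre-interaction
#' weight gap:
#' `Sim = pi/2 - atan(|Est_i - Est_p| / |(w_i_pre - w_p_pre) * DotNum|)`,
#' which lies in (0, pi/2]: pi/2 for identical estimates, pi/4 when the gap
#' equals the pre-interaction gap, approaching 0 as estimates diverge. When
#' the pre-interaction weights coincide the denominator vanishes; the
#' continuous limits are used (0 for a positive numerator, pi/2 for a zero
#' numerator).
#'
#' @param est_i,est_p participant and partner estimates.
#' @param dot_count dot magnitude(s), > 0.
#' @param w_i_pre participant pre-interaction weight.
#' @param w_p_pre partner initial weight (0.61 or 1.21).
#' @return similarity value(s) in (0, pi/2].
#' @export
compute_sim <- function(est_i, est_p, dot_count, w_i_pre, w_p_pre) {
  if (any(dot_count <= 0)) stop("dot_count must be positive")
  num <- abs(est_i - est_p)
  den <- abs((w_i_pre - w_p_pre) * dot_count)
  out <- ifelse(den == 0,
                ifelse(num > 0, 0, pi / 2),
                pi / 2 - atan(num / den))
  out
}

#' Build the lagged regressor set for one interaction session
#'
#' For trials `t >= 2` of a session (both estimates present), computes
#' `Atyp(t-1)` and `Sim(t-1)` together with the current dot count and
#' estimate.
#'
#' @param records one participant's interaction-phase trial records, in
#'   trial order, with `estimate` and `partner_estimate` present.
#' @param w_i_pre participant pre-interaction weight.
#' @param w_p_pre partner initial weight.
#' @param reference_weight normalizer of the atypicality regressor.
#' @return data.frame with `trial`, `dot_count`, `estimate`, `atyp_lag`,
#'   `sim_lag`; attributes `w_i_pre`, `w_p_pre`.
#' @export
build_regressors <- function(records, w_i_pre, w_p_pre,
                             reference_weight = 0.91) {
  records <- records[order(records$trial), , drop = FALSE]
  ok <- !is.na(records$estimate) & !is.na(records$partner_estimate)
  if (!all(ok)) records <- records[ok, , drop = FALSE]
  T <- nrow(records)
  if (T < 2) stop("need at least 2 complete trials")
  atyp <- compute_atyp(records$partner_estimate, records$dot_count,
                       reference_weight)
  sim <- compute_sim(records$estimate, records$partner_estimate,
                     records$dot_count, w_i_pre, w_p_pre)
  out <- data.frame(trial = records$trial[-1],
                    dot_count = records$dot_count[-1],
                    estimate = records$estimate[-1],
                    atyp_lag = atyp[-T], sim_lag = sim[-T])
  attr(out, "w_i_pre") <- w_i_pre
  attr(out, "w_p_pre") <- w_p_pre
  out
}

#' MCMC settings for the decomposition model
#'
#' Defaults reproduce the reported sampler configuration: four chains of
#' 20,000 iterations, the first 10,000 discarded, the remainder thinned by
#' 50 (200 kept draws per chain). Nominally unbounded uniform priors on the
#' trend/noise scales are truncated to `(0, scale_ub]` (coefficients are
#' order-one quantities) and the residual SD to `(0, sigma_eps_ub]` counts.
#'
#' @param chains number of chains.
#' @param iter total iterations per chain.
#' @param burnin discarded initial iterations per chain.
#' @param thin thinning interval.
#' @param prop_sd SD of log-scale Metropolis proposals.
#' @param scale_ub upper truncation for trend scales.
#' @param sigma_eps_ub upper truncation for the residual SD (counts).
#' @param sigma_baseline prior SD of the static Baseline about `w_i_pre`.
#' @param init_sd prior SD of the initial coefficient and trend states.
#' @return list of settings.
#' @export
decomposition_config <- function(chains = 4L, iter = 20000L, burnin = 10000L,
                                 thin = 50L, prop_sd = 0.4, scale_ub = 2,
                                 sigma_eps_ub = 25, sigma_baseline = 0.2,
                                 init_sd = 0.2) {
  list(chains = chains, iter = iter, burnin = burnin, thin = thin,
       prop_sd = prop_sd, scale_ub = scale_ub, sigma_eps_ub = sigma_eps_ub,
       sigma_baseline = sigma_baseline, init_sd = init_sd)
}

# Build the state-space matrices for a component set.
tvc_structure <- function(components) {
  has_b <- "baseline" %in% components
  has_a <- "atyp" %in% components
  has_s <- "sim" %in% components
  dims <- character(0)
  if (has_b) dims <- c(dims, "baseline")
  if (has_a) dims <- c(dims, "coef_atyp", "gamma_atyp")
  if (has_s) dims <- c(dims, "coef_sim", "gamma_sim")
  d <- length(dims)
  Tmat <- diag(1, d)
  rownames(Tmat) <- colnames(Tmat) <- dims
  if (has_a) Tmat["coef_atyp", "gamma_atyp"] <- 1
  if (has_s) Tmat["coef_sim", "gamma_sim"] <- 1
  scale_names <- setdiff(dims, "baseline")
  q_idx <- match(dims, scale_names) - 1L  # -1 encodes "no evolution noise"
  q_idx[is.na(q_idx)] <- -1L
  list(dims = dims, d = d, Tmat = Tmat, q_idx = as.integer(q_idx),
       scale_names = if (length(scale_names))
       paste0("sigma_", scale_names) else character(0),
       has_baseline = has_b, has_atyp = has_a, has_sim = has_s)
}

#' Fit the time-varying-coefficient decomposition
#'
#' Decomposes a participant's implied estimation weight during interaction
#' into a static Baseline plus time-varying Atypicality and Similarity
#' coefficients with local-linear-trend dynamics (see
#' [decomposition_config()] for the sampler). Reduced models are obtained
#' by dropping components; a model without a free Baseline pins it at
#' `w_i_pre`.
#'
#' @param records one participant's interaction-phase trial records (needs
#'   at least 20 complete trials), or a regressor set from
#'   [build_regressors()].
#' @param w_i_pre participant pre-interaction weight.
#' @param w_p_pre partner initial weight (0.61 or 1.21).
#' @param components subset of `c("baseline", "atyp", "sim")`; the full
#'   model keeps all three, `character(0)` is the null model.
#' @param reference_weight normalizer of the atypicality regressor.
#' @param config settings from [decomposition_config()].
#' @param seed integer seed; chains use `seed + chain`.
#' @param min_trials minimum complete interaction trials required.
#' @return object of class `decomposition_fit` with elements `summary`
#'   (posterior mean and 95% interval of the across-trial mean of
#'   `Coef_Sim`, residual SD, R-hat), `draws` (`loglik` kept-draws x trials
#'   matrix, `mean_coef_sim`, `sigma_eps`, `scales`), `states` (posterior
#'   means of the state paths), and the model description.
#' @export
fit_decomposition <- function(records, w_i_pre, w_p_pre,
                              components = c("baseline", "atyp", "sim"),
                              reference_weight = 0.91,
                              config = decomposition_config(), seed = 1L,
                              min_trials = 20L) {
  reg <- if (!is.null(attr(records, "w_i_pre"))) records
         else build_regressors(records, w_i_pre, w_p_pre, reference_weight)
  if (nrow(reg) + 1 < min_trials) {
    stop("need at least ", min_trials, " complete interaction trials")
  }
  stopifnot(all(components %in% c("baseline", "atyp", "sim")))
  st <- tvc_structure(components)
  m <- nrow(reg)
  y <- reg$estimate
  offset <- if (st$has_baseline) rep(0, m) else w_i_pre * reg$dot_count
  yadj <- y - offset
  Z <- matrix(0, m, max(st$d, 1))
  if (st$d > 0) {
    for (k in seq_len(st$d)) {
      Z[, k] <- switch(st$dims[k],
                       baseline = reg$dot_count,
                       coef_atyp = reg$dot_count * reg$atyp_lag,
                       coef_sim = reg$dot_count * reg$sim_lag,
                       0)
    }
  }
  a1 <- rep(0, st$d)
  p1 <- rep(config$init_sd, st$d)
  if (st$has_baseline) {
    a1[1] <- w_i_pre
    p1[1] <- config$sigma_baseline
  }
  n_scales <- length(st$scale_names)
  coef_sim_dim <- if (st$has_sim) which(st$dims == "coef_sim") - 1L else -1L

  keep <- (config$iter - config$burnin) %/% config$thin
  ll <- matrix(NA_real_, keep * config$chains, m)
  mcs <- matrix(NA_real_, keep, config$chains)
  eps <- matrix(NA_real_, keep, config$chains)
  scales <- array(NA_real_, c(keep, config$chains, max(n_scales, 1)))
  state_mean <- matrix(0, max(st$d, 1), m)
  for (ch in seq_len(config$chains)) {
    res <- with_seed(seed + ch, {
      init_scales <- exp(runif(max(n_scales, 1), log(0.01), log(0.2)))
      fitted0 <- if (st$d > 0) as.vector(Z %*% a1) else 0
      init_eps <- sd(yadj - fitted0) * exp(runif(1, -0.3, 0.3))
      if (!is.finite(init_eps) || init_eps <= 0) init_eps <- 1
      mcmc_tvc_cpp(yadj, Z, st$Tmat, st$q_idx, a1, p1,
                   n_scales, config$scale_ub, config$sigma_eps_ub,
                   config$iter, config$burnin, config$thin, config$prop_sd,
                   init_scales, max(init_eps, 0.5), coef_sim_dim)
    })
    ll[(ch - 1) * keep + seq_len(keep), ] <- res$loglik
    mcs[, ch] <- res$mean_coef_sim
    eps[, ch] <- res$sigma_eps
    scales[, ch, ] <- res$scales[, seq_len(max(n_scales, 1)), drop = FALSE]
    if (st$d > 0) state_mean <- state_mean + res$state_mean / config$chains
  }
  rownames(state_mean) <- if (st$d > 0) st$dims else NULL

  mean_coef_sim <- if (st$has_sim) mean(mcs) else NA_real_
  summ <- data.frame(
    model_tag = model_tag_for(components),
    mean_coef_sim = mean_coef_sim,
    mean_coef_sim_l95 = if (st$has_sim) unname(quantile(mcs, 0.025)) else NA,
    mean_coef_sim_u95 = if (st$has_sim) unname(quantile(mcs, 0.975)) else NA,
    sigma_eps_mean = mean(eps),
    rhat_sigma_eps = split_rhat(eps),
    rhat_mean_coef_sim = if (st$has_sim) split_rhat(mcs) else NA_real_)
  structure(list(summary = summ, components = components, structure = st,
                 draws = list(loglik = ll, mean_coef_sim = mcs,
                              sigma_eps = eps, scales = scales),
                 states = state_mean, regressors = reg,
                 offset = offset, Z = Z,
                 w_i_pre = w_i_pre, w_p_pre = w_p_pre, config = config),
            class = "decomposition_fit")
}

model_tag_for <- function(components) {
  has <- c(baseline = "baseline" %in% components,
           atyp = "atyp" %in% components,
           sim = "sim" %in% components)
  if (all(has)) return("full")
  if (!any(has)) return("null")
  paste(names(has)[has], collapse = "+")
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat("<decomposition_fit>", x$summary$model_tag, "model,",
      nrow(x$regressors), "trials\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_t log mean_s exp(ll[s, t])`,
#' `p_waic = sum_t var_s(ll[s, t])` (sample variance across draws),
#' `waic = -2 (lppd - p_waic)`.
#'
#' @param pointwise_loglik draws x trials matrix of log-likelihood values.
#' @param model_tag optional label.
#' @return object of class `waic_result` with `lppd`, `p_waic`, `waic`.
#' @export
compute_waic <- function(pointwise_loglik, model_tag = NA_character_) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2 || ncol(ll) < 1) stop("need >= 2 draws and >= 1 trial")
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  lppd <- sum(apply(ll, 2, function(x) {
    mx <- max(x)
    mx + log(mean(exp(x - mx)))
  }))
  p_waic <- sum(apply(ll, 2, var))
  structure(list(model_tag = model_tag, lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("<waic_result> %s: WAIC = %.2f (lppd %.2f, p_waic %.2f)\n",
              x$model_tag, x$waic, x$lppd, x$p_waic))
  invisible(x)
}

MODEL_LADDER <- list(
  full = c("baseline", "atyp", "sim"),
  null = character(0),
  baseline = "baseline",
  atyp = "atyp",
  sim = "sim",
  `baseline+atyp` = c("baseline", "atyp"),
  `baseline+sim` = c("baseline", "sim"),
  `atyp+sim` = c("atyp", "sim"))

#' Fit the full model and its seven reductions and compare by WAIC
#'
#' The reduced models drop Baseline, Atypicality, and/or Similarity from
#' the decomposition (the null model keeps none: the weight is pinned at
#' `w_i_pre` and only the residual SD is estimated).
#'
#' @inheritParams fit_decomposition
#' @return data.frame of 8 rows (`model`, `lppd`, `p_waic`, `waic`), ranked
#'   by WAIC; attribute `"fits"` keeps the fitted objects.
#' @export
model_ladder_fit <- function(records, w_i_pre, w_p_pre,
                             reference_weight = 0.91,
                             config = decomposition_config(), seed = 1L) {
  reg <- if (!is.null(attr(records, "w_i_pre"))) records
         else build_regressors(records, w_i_pre, w_p_pre, reference_weight)
  fits <- lapply(names(MODEL_LADDER), function(tag) {
    fit_decomposition(reg, w_i_pre, w_p_pre,
                      components = MODEL_LADDER[[tag]], config = config,
                      seed = seed)
  })
  names(fits) <- names(MODEL_LADDER)
  tab <- do.call(rbind, lapply(names(fits), function(tag) {
    wr <- compute_waic(fits[[tag]]$draws$loglik, tag)
    data.frame(model = tag, lppd = wr$lppd, p_waic = wr$p_waic,
               waic = wr$waic)
  }))
  tab <- tab[order(tab$waic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Posterior predictive check
#'
#' Predicts each trial's estimate from the posterior-mean state paths and
#' reports the Pearson correlation with the observed estimates.
#'
#' @param fit a `decomposition_fit`.
#' @return list with `r` (`NA` with a warning when predictions have zero
#'   variance), `predicted`, and `observed`.
#' @export
posterior_predictive_check <- function(fit) {
  stopifnot(inherits(fit, "decomposition_fit"))
  m <- nrow(fit$regressors)
  pred <- fit$offset +
    if (fit$structure$d > 0) rowSums(fit$Z * t(fit$states)) else rep(0, m)
  obs <- fit$regressors$estimate
  if (sd(pred) == 0) {
    warning("predicted estimates have zero variance; correlation undefined")
    return(list(r = NA_real_, predicted = pred, observed = obs))
  }
  list(r = cor(obs, pred), predicted = pred, observed = obs)
}

#' Simulate an interaction session from the decomposition model
#'
#' Generates one participant x partner session directly from the
#' time-varying-coefficient model: the participant's weight on trial `t` is
#' `baseline + coef_atyp(t) * Atyp(t-1) + coef_sim(t) * Sim(t-1)` and the
#' estimate is that weight times the dot count plus `N(0, sigma_eps)` noise
#' (trial 1, which has no lagged regressors, uses the baseline alone). The
#' partner is a computer agent. Estimates are left real-valued by default
#' so that recovery checks are not confounded by discretization.
#'
#' @param dots integer vector of dot magnitudes.
#' @param agent partner [agent_config()].
#' @param w_i_pre participant pre-interaction (baseline) weight.
#' @param coef_sim,coef_atyp scalar or per-trial vector coefficient paths.
#' @param baseline participant baseline (defaults to `w_i_pre`).
#' @param sigma_eps residual SD in counts.
#' @param reference_weight atypicality normalizer.
#' @param seed integer seed.
#' @param round_estimates emit integer estimates (floored at 1) if `TRUE`.
#' @return trial-record data.frame with both estimates; attribute
#'   `"regressors"` has the realized `Atyp`/`Sim` series.
#' @export
simulate_decomposition_session <- function(dots, agent, w_i_pre = 0.91,
                                           coef_sim = 0, coef_atyp = 0,
                                           baseline = w_i_pre,
                                           sigma_eps = 2,
                                           reference_weight = 0.91,
                                           seed = NULL,
                                           round_estimates = FALSE) {
  n <- length(dots)
  coef_sim <- rep_len(coef_sim, n)
  coef_atyp <- rep_len(coef_atyp, n)
  with_seed(seed, {
    est_i <- numeric(n)
    est_p <- numeric(n)
    atyp <- numeric(n)
    sim <- numeric(n)
    state <- if (agent$partner_type == "sherif") sherif_init_state(agent)
    for (t in seq_len(n)) {
      w_t <- if (t == 1) baseline else {
        baseline + coef_atyp[t] * atyp[t - 1] + coef_sim[t] * sim[t - 1]
      }
      e <- w_t * dots[t] + if (sigma_eps > 0) rnorm(1, 0, sigma_eps) else 0
      est_i[t] <- if (round_estimates) max(1, round_half_away(e)) else e
      if (agent$partner_type == "asch") {
        est_p[t] <- asch_estimate(agent, dots[t])
      } else {
        out <- sherif_estimate(agent, state, dots[t])
        est_p[t] <- out$estimate
        state <- observe_participant(out$state, est_i[t], dots[t])
      }
      atyp[t] <- compute_atyp(est_p[t], dots[t], reference_weight)
      sim[t] <- compute_sim(est_i[t], est_p[t], dots[t], w_i_pre,
                            agent$initial_weight)
    }
    rec <- data.frame(participant_id = "SIM", condition = agent$partner_type,
                      phase = "interaction", trial = seq_len(n),
                      dot_count = as.integer(dots), estimate = est_i,
                      partner_estimate = est_p)
    attr(rec, "regressors") <- data.frame(trial = seq_len(n), atyp = atyp,
                                          sim = sim)
    rec
  })
}
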