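#' Build per-trial weight series from trial records
#'
#' The observed per-trial weight is `estimate / dot_count`, taken in trial
#' order after removing missing estimates. Series with fewer than
#' `min_trials` usable trials are excluded with a warning (they carry too
#' little information for the state-space fit).
#'
#' @param records trial-record data.frame (ideally cleaned with
#'   [clean_trials()]).
#' @param min_trials minimum usable trials per series (default 8).
#' @return list of weight series; each element is a list with
#'   `participant_id`, `phase`, and numeric `w_obs`.
#' @export
build_weight_series <- function(records, min_trials = 8L) {
  cells <- unique(records[c("participant_id", "phase")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- records[records$participant_id == cells$participant_id[r] &
                   records$phase == cells$phase[r], , drop = FALSE]
    sub <- sub[order(sub$trial), , drop = FALSE]
    sub <- sub[!is.na(sub$estimate), , drop = FALSE]
    w <- sub$estimate / sub$dot_count
    if (length(w) < min_trials) {
      warning("series ", cells$participant_id[r], "/", cells$phase[r],
              " has fewer than ", min_trials, " usable trials; excluded")
      next
    }
    out[[length(out) + 1]] <- list(participant_id = cells$participant_id[r],
                                   phase = cells$phase[r], w_obs = w)
  }
  out
}

#' Marginal log-likelihood of the local-level model
#'
#' Log-likelihood of an observed weight series under
#' `w(t) ~ N(mu(t), sigma_obs)`, `mu(t) ~ N(mu(t-1), sigma_mu)`,
#' `mu(1) ~ N(mu1_mean, mu1_sd)`, with the latent path integrated out.
#' Two independent routes are provided: the Kalman-filter prediction-error
#' decomposition (`"kalman"`, the one used internally) and a direct dense
#' multivariate-normal evaluation of the implied joint covariance
#' (`"direct"`), useful as a cross-check.
#'
#' @param w numeric weight series.
#' @param sigma_obs,sigma_mu observation- and system-noise SDs.
#' @param mu1_mean,mu1_sd prior mean and SD of the initial latent state
#'   (defaults: first observation, 0.5).
#' @param method `"kalman"` or `"direct"`.
#' @return scalar log-likelihood.
#' @export
local_level_loglik <- function(w, sigma_obs, sigma_mu,
                               mu1_mean = w[1], mu1_sd = 0.5,
                               method = c("kalman", "direct")) {
  method <- match.arg(method)
  if (method == "kalman") {
    return(kalman_loglik_cpp(w, sigma_obs, sigma_mu, mu1_mean, mu1_sd))
  }
  T <- length(w)
  idx <- seq_len(T)
  # Cov(mu_t, mu_s) = mu1_sd^2 + sigma_mu^2 * (min(t, s) - 1)
  Sigma <- mu1_sd^2 + sigma_mu^2 * (outer(idx, idx, pmin) - 1)
  Sigma <- Sigma + diag(sigma_obs^2, T)
  ch <- chol(Sigma)
  z <- backsolve(ch, w - mu1_mean, transpose = TRUE)
  -0.5 * T * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' MCMC settings for the stability model
#'
#' Defaults reproduce the reported sampler configuration: four chains, 1000
#' kept draws per chain after a 500-iteration burn-in. The nominally
#' unbounded uniform priors are truncated to proper ranges: `[0, sd_ub]`
#' for all SDs and `[mean_lb, mean_ub]` for group means (estimation weights
#' live near 1, so these bounds are materially uninformative).
#'
#' @param chains number of chains.
#' @param iter kept draws per chain.
#' @param burnin discarded initial iterations per chain.
#' @param thin thinning interval applied after burn-in.
#' @param prop_sd SD of the log-scale Metropolis proposals.
#' @param sd_ub upper truncation for SD parameters.
#' @param mean_lb,mean_ub truncation for group-mean parameters.
#' @param mu1_sd prior SD of the initial latent state.
#' @return list of settings.
#' @export
mcmc_config <- function(chains = 4L, iter = 1000L, burnin = 500L, thin = 1L,
                        prop_sd = 0.25, sd_ub = 5, mean_lb = -5, mean_ub = 5,
                        mu1_sd = 0.5) {
  list(chains = chains, iter = iter, burnin = burnin, thin = thin,
       prop_sd = prop_sd, sd_ub = sd_ub, mean_lb = mean_lb,
       mean_ub = mean_ub, mu1_sd = mu1_sd)
}

#' Fit the hierarchical stability model to one phase
#'
#' Gibbs sampler for the hierarchical local-level model: latent paths are
#' drawn by forward-filtering backward-sampling, per-participant noise SDs
#' by log-scale Metropolis steps under truncated-normal group
#' distributions, and the group hyperparameters by Metropolis steps. The
#' per-participant posterior mean of the system-noise SD `sigma_mu` is the
#' stability index. With a single series the group layer is dropped and
#' uniform priors are used.
#'
#' @param series list of weight series from [build_weight_series()] (all
#'   from one phase), or a single numeric vector.
#' @param config settings from [mcmc_config()].
#' @param seed integer seed; chains use `seed + chain`.
#' @return object of class `stability_fit`: `summary` (one row per
#'   participant: posterior mean and central 95% interval of `sigma_mu`,
#'   posterior mean of `sigma_obs`, R-hat, effective sample size),
#'   `group` (draws of the four group hyperparameters), `draws`
#'   (iterations x chains x participants arrays), `reliable` (all
#'   R-hat <= 1.05).
#' @export
fit_stability <- function(series, config = mcmc_config(), seed = 1L) {
  if (is.numeric(series)) {
    series <- list(list(participant_id = "P1", phase = "phase", w_obs = series))
  }
  n <- length(series)
  if (n == 0) stop("no usable weight series")
  ids <- vapply(series, `[[`, character(1), "participant_id")
  w_list <- lapply(series, `[[`, "w_obs")
  hierarchical <- n >= 2
  n_iter <- config$burnin + config$iter * config$thin

  keep <- config$iter
  arr_mu <- array(NA_real_, c(keep, config$chains, n))
  arr_obs <- array(NA_real_, c(keep, config$chains, n))
  arr_group <- array(NA_real_, c(keep, config$chains, 4))
  paths <- NULL
  for (ch in seq_len(config$chains)) {
    res <- with_seed(seed + ch, {
      init_obs <- vapply(w_list, function(w) {
        max(0.02, sd(diff(w)) / sqrt(2)) * exp(runif(1, -0.4, 0.4))
      }, numeric(1))
      init_mu <- init_obs * exp(runif(n, -1, 0.2))
      mcmc_local_level_cpp(w_list, n_iter, config$burnin, config$thin,
                           config$sd_ub, config$mean_lb, config$mean_ub,
                           config$mu1_sd, hierarchical, config$prop_sd,
                           init_obs, init_mu,
                           mean(init_obs), 0.5 * mean(init_obs) + 0.02,
                           mean(init_mu), 0.5 * mean(init_mu) + 0.02)
    })
    arr_mu[, ch, ] <- res$sigma_mu
    arr_obs[, ch, ] <- res$sigma_obs
    arr_group[, ch, ] <- res$group
    if (ch == 1) {
      paths <- lapply(seq_len(n), function(i) {
        data.frame(trial = seq_along(res$path_mean[[i]]),
                   mu_mean = as.numeric(res$path_mean[[i]]),
                   mu_sd = as.numeric(res$path_sd[[i]]))
      })
    }
  }

  summ <- do.call(rbind, lapply(seq_len(n), function(i) {
    dr <- as.numeric(arr_mu[, , i])
    data.frame(participant_id = ids[i],
               phase = series[[i]]$phase,
               sigma_mean = mean(dr),
               sigma_l95 = unname(quantile(dr, 0.025)),
               sigma_u95 = unname(quantile(dr, 0.975)),
               sigma_obs_mean = mean(as.numeric(arr_obs[, , i])),
               rhat = split_rhat(arr_mu[, , i]),
               ess = ess_basic(dr))
  }))
  group_names <- c("gmu_obs", "gsd_obs", "gmu_mu", "gsd_mu")
  group <- do.call(rbind, lapply(1:4, function(j) {
    dr <- as.numeric(arr_group[, , j])
    data.frame(parameter = group_names[j], mean = mean(dr),
               l95 = unname(quantile(dr, 0.025)),
               u95 = unname(quantile(dr, 0.975)),
               rhat = split_rhat(arr_group[, , j]))
  }))
  reliable <- all(is.na(summ$rhat) | summ$rhat <= 1.05)
  if (!reliable) {
    warning("stability fit may be unreliable: max R-hat = ",
            round(max(summ$rhat, na.rm = TRUE), 3))
  }
  structure(list(summary = summ, group = group,
                 draws = list(sigma_mu = arr_mu, sigma_obs = arr_obs,
                              group = arr_group),
                 paths = paths, participants = ids,
                 hierarchical = hierarchical, reliable = reliable,
                 config = config),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat("<stability_fit>", length(x$participants), "participant(s),",
      if (x$hierarchical) "hierarchical" else "non-hierarchical", "\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pre/post change in the stability index
#'
#' Posterior-mean difference of `sigma_mu` (post minus pre) per participant;
#' negative values indicate a stabilized (less noisy) estimation weight.
#'
#' @param pre,post `stability_fit` objects with matching participant ids.
#' @return data.frame with `participant_id` and `delta_sigma`.
#' @export
delta_sigma <- function(pre, post) {
  stopifnot(inherits(pre, "stability_fit"), inherits(post, "stability_fit"))
  if (!setequal(pre$participants, post$participants)) {
    stop("participant ids do not match between pre and post fits")
  }
  pre_s <- pre$summary
  post_s <- post$summary[match(pre_s$participant_id,
                               post$summary$participant_id), ]
  data.frame(participant_id = pre_s$participant_id,
             delta_sigma = post_s$sigma_mean - pre_s$sigma_mean)
}
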