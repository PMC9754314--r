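#' Simulate a solo (non-interactive) phase
#'
#' The participant's latent weight follows a Gaussian random walk with SD
#' `sigma_mu_true` starting from `start_weight` (defaults to the
#' participant's `base_weight`); the per-trial realized weight adds
#' observation noise `sigma_obs_true`; the emitted estimate is
#' `round(weight * dots)` plus rounded Gaussian estimate noise, clipped to
#' be at least 1.
#'
#' @param participant a [virtual_participant()].
#' @param phase one phase of a [make_schedule()] object (non-interactive).
#' @param seed integer seed.
#' @param condition condition label written into the records.
#' @param start_weight latent weight entering the phase; defaults to
#'   `participant$base_weight`. The final latent weight is attached as
#'   attribute `"final_weight"` so phases can be chained.
#' @return data.frame of trial records (one row per trial) with columns
#'   `participant_id`, `condition`, `phase`, `trial`, `dot_count`,
#'   `estimate`, `partner_estimate` (all `NA` here).
#' @export
simulate_solo_phase <- function(participant, phase, seed = NULL,
                                condition = "solo", start_weight = NULL) {
  stopifnot(inherits(participant, "virtual_participant"))
  if (isTRUE(phase$interaction)) {
    stop("simulate_solo_phase() requires a non-interactive phase")
  }
  start_mu <- if (is.null(start_weight)) participant$base_weight else start_weight
  with_seed(seed, {
    out <- sim_solo_core(participant, phase$dot_counts, start_mu)
    rec <- trial_records(participant$id, condition, phase$phase_label,
                         phase$dot_counts, out$estimate, NA_integer_)
    attr(rec, "final_weight") <- out$mu[length(out$mu)]
    rec
  })
}

#' Simulate an interaction phase against a computer partner or a second
#' participant
#'
#' Both sides view the same dots and estimate independently; estimates are
#' then shared. The participant's latent weight follows the same lag-5
#' reciprocating recurrence used by the Sherif-type agent,
#' `mu(t) = c + sum_j a_j mu(t-j) + sum_j b_j w_partner(t-j) + system noise`,
#' with the intercept `c = mu_entry * (1 - sum(a) - sum(b))` anchored so the
#' recurrence's fixed point is the weight the participant entered the phase
#' with when the partner matches it. Participants with
#' `reciprocity_coeffs = NULL` (or all-zero coefficients) reduce to the solo
#' random walk. Partner implied weights are `estimate / dot_count`.
#'
#' @param participant a [virtual_participant()].
#' @param partner an [agent_config()] or a second [virtual_participant()].
#' @param phase one phase of a [make_schedule()] object.
#' @param seed integer seed.
#' @param condition condition label; defaults to the partner type.
#' @param start_weight,partner_start_weight latent weights entering the
#'   phase (default: each side's `base_weight`).
#' @return data.frame of the participant's trial records with
#'   `partner_estimate` filled; attributes `"final_weight"` and, when the
#'   partner is a virtual participant, `"partner_records"` and
#'   `"partner_final_weight"`.
#' @export
simulate_interaction_phase <- function(participant, partner, phase,
                                       seed = NULL, condition = NULL,
                                       start_weight = NULL,
                                       partner_start_weight = NULL) {
  stopifnot(inherits(participant, "virtual_participant"))
  start_mu <- if (is.null(start_weight)) participant$base_weight else start_weight
  with_seed(seed, {
    if (inherits(partner, "agent_config")) {
      condition <- condition %||% partner$partner_type
      out <- sim_vs_agent_core(participant, partner, phase$dot_counts, start_mu)
      rec <- trial_records(participant$id, condition, phase$phase_label,
                           phase$dot_counts, out$est_i, out$est_p)
      attr(rec, "final_weight") <- out$final_mu
      rec
    } else if (inherits(partner, "virtual_participant")) {
      condition <- condition %||% "pair"
      start_mu2 <- if (is.null(partner_start_weight)) partner$base_weight
                   else partner_start_weight
      out <- sim_dyad_core(participant, partner, phase$dot_counts,
                           start_mu, start_mu2)
      rec <- trial_records(participant$id, condition, phase$phase_label,
                           phase$dot_counts, out$est1, out$est2)
      prec <- trial_records(partner$id, condition, phase$phase_label,
                            phase$dot_counts, out$est2, out$est1)
      attr(rec, "final_weight") <- out$final_mu1
      attr(rec, "partner_records") <- prec
      attr(rec, "partner_final_weight") <- out$final_mu2
      rec
    } else {
      stop("partner must be an agent_config or a virtual_participant")
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trial_records <- function(id, condition, phase, dots, est, est_p) {
  data.frame(participant_id = id, condition = condition, phase = phase,
             trial = seq_along(dots), dot_count = as.integer(dots),
             estimate = as.integer(est),
             partner_estimate = as.integer(est_p))
}

# --- internal cores (RNG handled by callers) ---------------------------------

emit_estimate <- function(p, weight, dot) {
  noise <- if (p$estimate_noise_sd > 0)
    round_half_away(rnorm(1, 0, p$estimate_noise_sd)) else 0
  max(1L, as.integer(round_half_away(weight * dot) + noise))
}

sim_solo_core <- function(p, dots, start_mu) {
  n <- length(dots)
  mu <- numeric(n)
  est <- integer(n)
  m <- start_mu
  for (t in seq_len(n)) {
    if (t > 1 && p$sigma_mu_true > 0) m <- m + rnorm(1, 0, p$sigma_mu_true)
    mu[t] <- m
    w <- m + if (p$sigma_obs_true > 0) rnorm(1, 0, p$sigma_obs_true) else 0
    est[t] <- emit_estimate(p, w, dots[t])
  }
  list(estimate = est, mu = mu)
}

recip_or_zero <- function(p) {
  p$reciprocity_coeffs %||% list(a = rep(0, 5), b = rep(0, 5))
}

# One reciprocating latent step; histories are most-recent-first.
recip_step <- function(cc, intercept, own_hist, partner_hist, sigma_mu) {
  m <- intercept + sum(cc$a * own_hist) + sum(cc$b * partner_hist)
  if (sigma_mu > 0) m <- m + rnorm(1, 0, sigma_mu)
  m
}

sim_vs_agent_core <- function(p, agent, dots, start_mu) {
  n <- length(dots)
  cc <- recip_or_zero(p)
  intercept <- start_mu * (1 - sum(cc$a) - sum(cc$b))
  own_hist <- rep(start_mu, 5)
  partner_hist <- rep(start_mu, 5)
  astate <- if (agent$partner_type == "sherif") sherif_init_state(agent)
  est_i <- integer(n)
  est_p <- integer(n)
  m <- start_mu
  for (t in seq_len(n)) {
    m <- recip_step(cc, intercept, own_hist, partner_hist, p$sigma_mu_true)
    w <- m + if (p$sigma_obs_true > 0) rnorm(1, 0, p$sigma_obs_true) else 0
    est_i[t] <- emit_estimate(p, w, dots[t])
    if (agent$partner_type == "asch") {
      est_p[t] <- asch_estimate(agent, dots[t])
    } else {
      out <- sherif_estimate(agent, astate, dots[t])
      est_p[t] <- out$estimate
      astate <- observe_participant(out$state, est_i[t], dots[t])
    }
    own_hist <- push_lag(own_hist, m)
    partner_hist <- push_lag(partner_hist, est_p[t] / dots[t])
  }
  list(est_i = est_i, est_p = est_p, final_mu = m)
}

sim_dyad_core <- function(p1, p2, dots, start_mu1, start_mu2) {
  n <- length(dots)
  cc1 <- recip_or_zero(p1)
  cc2 <- recip_or_zero(p2)
  ic1 <- start_mu1 * (1 - sum(cc1$a) - sum(cc1$b))
  ic2 <- start_mu2 * (1 - sum(cc2$a) - sum(cc2$b))
  own1 <- rep(start_mu1, 5); part1 <- rep(start_mu1, 5)
  own2 <- rep(start_mu2, 5); part2 <- rep(start_mu2, 5)
  est1 <- integer(n); est2 <- integer(n)
  m1 <- start_mu1; m2 <- start_mu2
  for (t in seq_len(n)) {
    m1 <- recip_step(cc1, ic1, own1, part1, p1$sigma_mu_true)
    m2 <- recip_step(cc2, ic2, own2, part2, p2$sigma_mu_true)
    w1 <- m1 + if (p1$sigma_obs_true > 0) rnorm(1, 0, p1$sigma_obs_true) else 0
    w2 <- m2 + if (p2$sigma_obs_true > 0) rnorm(1, 0, p2$sigma_obs_true) else 0
    est1[t] <- emit_estimate(p1, w1, dots[t])
    est2[t] <- emit_estimate(p2, w2, dots[t])
    own1 <- push_lag(own1, m1); part1 <- push_lag(part1, est2[t] / dots[t])
    own2 <- push_lag(own2, m2); part2 <- push_lag(part2, est1[t] / dots[t])
  }
  list(est1 = est1, est2 = est2, final_mu1 = m1, final_mu2 = m2)
}
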