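#' Configure a computer partner
#'
#' Two partner types are available, mirroring the programmed agents used in
#' the scanner and online experiments:
#'
#' * **Asch-type** (unresponsive): estimates `round(w * dots) + eta` with a
#'   fixed built-in weight `w` (0.61 for the underestimator, 1.21 for the
#'   overestimator) and integer noise `eta` drawn uniformly from
#'   `eta_support`.
#' * **Sherif-type** (reciprocating): its weight on trial `t` is the lag-5
#'   affine recurrence
#'   `w_p(t) = intercept + sum_j a_j w_p(t-j) + sum_j b_j w_i(t-j)`,
#'   where `w_i(t-j)` is the participant's implied weight
#'   (estimate / dot count) on preceding trials. The default coefficients
#'   are the values fitted to the laboratory pairs; note the intercept 0.61
#'   is numerically unrelated to the built-in bias 0.61.
#'
#' For an overestimating Sherif partner the recurrence intercept is either
#' kept at its fitted value with only the warm-start histories moved to
#' `initial_weight` (`intercept_mode = "history"`, the default) or rescaled
#' so the recurrence's fixed point against a `participant_pre`-weighted
#' partner reproduces `initial_weight`
#' (`intercept_mode = "rescale"`).
#'
#' @param partner_type `"asch"` or `"sherif"`.
#' @param initial_weight built-in estimation weight (0.61 or 1.21).
#' @param eta_support integer support of the additive estimate noise.
#' @param intercept intercept of the Sherif recurrence.
#' @param a,b lag-5 coefficient vectors of the Sherif recurrence.
#' @param intercept_mode `"history"` or `"rescale"` (Sherif only).
#' @param participant_pre assumed participant pre-interaction weight used to
#'   warm-start the participant-side lag buffer.
#' @return object of class `agent_config`.
#' @examples
#' cfg <- agent_config("asch", initial_weight = 0.61)
#' @export
agent_config <- function(partner_type = c("asch", "sherif"),
                         initial_weight = 0.61,
                         eta_support = -2:2,
                         intercept = 0.61,
                         a = default_reciprocity_coeffs()$a,
                         b = default_reciprocity_coeffs()$b,
                         intercept_mode = c("history", "rescale"),
                         participant_pre = 0.91) {
  partner_type <- match.arg(partner_type)
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(length(a) == 5, length(b) == 5,
            length(eta_support) >= 1,
            all(eta_support == as.integer(eta_support)),
            initial_weight > 0)
  if (partner_type == "sherif" && intercept_mode == "rescale") {
    intercept <- initial_weight * (1 - sum(a)) - sum(b) * participant_pre
  }
  structure(list(partner_type = partner_type,
                 initial_weight = initial_weight,
                 eta_support = as.integer(eta_support),
                 intercept = intercept, a = a, b = b,
                 intercept_mode = intercept_mode,
                 participant_pre = participant_pre),
            class = "agent_config")
}

#' Initialize the lag buffers of a Sherif-type partner
#'
#' Both five-trial histories are warm-started: the agent's own buffer with
#' its built-in `initial_weight`, the participant's buffer with
#' `participant_pre`, so the recurrence can act from the first trial while
#' reproducing the programmed initial bias.
#'
#' @param config an [agent_config()] with `partner_type = "sherif"`.
#' @return list with `w_history` and `partner_w_history` (most recent first).
#' @export
sherif_init_state <- function(config) {
  stopifnot(inherits(config, "agent_config"))
  list(w_history = rep(config$initial_weight, 5),
       partner_w_history = rep(config$participant_pre, 5))
}

#' Asch-type estimate
#'
#' `round(initial_weight * dot_count)` (half away from zero) plus integer
#' noise drawn uniformly from the configured support, floored at 1.
#'
#' @param config an [agent_config()] with `partner_type = "asch"`.
#' @param dot_count integer dot magnitude.
#' @return integer estimate.
#' @export
asch_estimate <- function(config, dot_count) {
  stopifnot(config$partner_type == "asch")
  eta <- if (length(config$eta_support) == 1) config$eta_support else
    sample(config$eta_support, 1)
  max(1L, as.integer(round_half_away(config$initial_weight * dot_count) + eta))
}

#' Sherif-type weight update
#'
#' Evaluates the lag-5 affine recurrence on the current histories and shifts
#' the agent's own history by one lag.
#'
#' @param config an [agent_config()] with `partner_type = "sherif"`.
#' @param state state list from [sherif_init_state()].
#' @return list with `weight` (the new `w_p(t)`) and the updated `state`.
#' @export
sherif_update_weight <- function(config, state) {
  stopifnot(config$partner_type == "sherif")
  if (!all(is.finite(c(state$w_history, state$partner_w_history)))) {
    stop("non-finite values in Sherif lag histories")
  }
  w <- config$intercept +
    sum(config$a * state$w_history) +
    sum(config$b * state$partner_w_history)
  state$w_history <- push_lag(state$w_history, w)
  list(weight = w, state = state)
}

#' Sherif-type estimate
#'
#' Updates the agent weight via [sherif_update_weight()], then emits
#' `round(w_p(t) * dot_count) + eta`, floored at 1. Noise is added after
#' rounding the deterministic part so estimates are integers by
#' construction.
#'
#' @inheritParams asch_estimate
#' @param state state list from [sherif_init_state()].
#' @return list with `estimate`, `weight`, and the updated `state`.
#' @export
sherif_estimate <- function(config, state, dot_count) {
  upd <- sherif_update_weight(config, state)
  eta <- if (length(config$eta_support) == 1) config$eta_support else
    sample(config$eta_support, 1)
  est <- max(1L, as.integer(round_half_away(upd$weight * dot_count) + eta))
  list(estimate = est, weight = upd$weight, state = upd$state)
}

#' Record the participant's estimate in a Sherif-type partner's state
#'
#' Pushes the participant's implied weight, `estimate / dot_count`, onto the
#' participant-side lag buffer.
#'
#' @param state state list from [sherif_init_state()].
#' @param participant_estimate the participant's integer estimate.
#' @param dot_count dot magnitude of the shared trial (> 0).
#' @return updated state.
#' @export
observe_participant <- function(state, participant_estimate, dot_count) {
  if (dot_count <= 0) stop("dot_count must be positive")
  state$partner_w_history <- push_lag(state$partner_w_history,
                                      participant_estimate / dot_count)
  state
}

#' Run a computer partner over a schedule phase against a fixed trace
#'
#' Convenience driver: replays a participant estimate trace (or none, for an
#' Asch-type partner) and returns the partner's estimates trial by trial.
#'
#' @param config an [agent_config()].
#' @param dot_counts integer vector of dot magnitudes.
#' @param participant_estimates optional numeric vector (required for
#'   Sherif-type partners), the participant estimate on each trial.
#' @param seed integer seed for the eta noise.
#' @return data.frame with `trial`, `dot_count`, `estimate`, `weight`.
#' @export
run_agent <- function(config, dot_counts, participant_estimates = NULL,
                      seed = NULL) {
  n <- length(dot_counts)
  if (config$partner_type == "sherif" && is.null(participant_estimates)) {
    stop("a Sherif-type partner needs the participant's estimate trace")
  }
  with_seed(seed, {
    est <- integer(n)
    wgt <- numeric(n)
    state <- if (config$partner_type == "sherif") sherif_init_state(config)
    for (t in seq_len(n)) {
      if (config$partner_type == "asch") {
        est[t] <- asch_estimate(config, dot_counts[t])
        wgt[t] <- config$initial_weight
      } else {
        out <- sherif_estimate(config, state, dot_counts[t])
        est[t] <- out$estimate
        wgt[t] <- out$weight
        state <- observe_participant(out$state, participant_estimates[t],
                                     dot_counts[t])
      }
    }
    data.frame(trial = seq_len(n), dot_count = dot_counts,
               estimate = est, weight = wgt)
  })
}
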