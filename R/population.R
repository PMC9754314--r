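#' Population parameters for virtual participants' estimation weights
#'
#' Mean and SD of the normal distribution from which virtual participants'
#' baseline estimation weights are drawn. The mean (0.915) is the mean
#' Phase-1 weight observed in the laboratory experiment; the SD is derived
#' from the fact that the computer partners' built-in bias of 0.61 sat 1.5
#' SD below that mean, giving (0.915 - 0.61) / 1.5.
#'
#' @return list with `mean_weight` and `sd_weight`.
#' @examples
#' default_population_params()
#' @export
default_population_params <- function() {
  list(mean_weight = 0.915, sd_weight = (0.915 - 0.61) / 1.5)
}

#' Default reciprocity coefficients
#'
#' Lag-5 coefficients of the reciprocating update rule,
#' `w(t) = c + sum_j a_j w_own(t-j) + sum_j b_j w_partner(t-j)`,
#' as fitted to the 21 laboratory pairs. `a` weighs the agent's (or
#' participant's) own recent weights, `b` the counterpart's implied weights.
#'
#' @return list with numeric vectors `a` and `b`, each of length 5.
#' @export
default_reciprocity_coeffs <- function() {
  list(a = c(0.091, 0.044, 0.037, 0.032, 0.025),
       b = c(0.066, 0.014, 0.001, -0.015, -0.011))
}

#' Create a virtual participant
#'
#' A virtual participant is defined by a baseline psychophysical weight and
#' three noise scales: per-trial system noise on the latent weight
#' (`sigma_mu_true`, the quantity the stability model recovers), observation
#' noise on the realized weight (`sigma_obs_true`), and additive Gaussian
#' noise on the integer estimate in units of counts (`estimate_noise_sd`).
#' `reciprocity_coeffs` (lag-5 `a`/`b` lists) govern adjustment toward a
#' partner during interaction phases; `NULL` means non-reciprocating.
#'
#' @param id participant label.
#' @param base_weight baseline estimation weight (> 0).
#' @param sigma_mu_true system-noise SD per trial (>= 0).
#' @param sigma_obs_true observation-noise SD (>= 0).
#' @param estimate_noise_sd SD of additive estimate noise in counts (>= 0).
#' @param reciprocity_coeffs `NULL` or a list with lag-5 vectors `a`, `b`.
#' @return object of class `virtual_participant`.
#' @export
virtual_participant <- function(id, base_weight,
                                sigma_mu_true = 0.01,
                                sigma_obs_true = 0.05,
                                estimate_noise_sd = 2,
                                reciprocity_coeffs = default_reciprocity_coeffs()) {
  stopifnot(length(base_weight) == 1, base_weight > 0,
            sigma_mu_true >= 0, sigma_obs_true >= 0, estimate_noise_sd >= 0)
  if (!is.null(reciprocity_coeffs)) {
    stopifnot(length(reciprocity_coeffs$a) == 5,
              length(reciprocity_coeffs$b) == 5)
  }
  structure(list(id = as.character(id), base_weight = base_weight,
                 sigma_mu_true = sigma_mu_true,
                 sigma_obs_true = sigma_obs_true,
                 estimate_noise_sd = estimate_noise_sd,
                 reciprocity_coeffs = reciprocity_coeffs),
            class = "virtual_participant")
}

#' Sample a population of virtual participants
#'
#' Baseline weights are drawn from the population normal distribution (see
#' [default_population_params()]) truncated below at 0.05 so every weight is
#' strictly positive.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @param params list with `mean_weight`, `sd_weight`.
#' @param id_prefix prefix for generated ids.
#' @param ... further arguments passed to [virtual_participant()].
#' @return list of `virtual_participant` objects.
#' @export
sample_participants <- function(n, seed = 1L,
                                params = default_population_params(),
                                id_prefix = "P", ...) {
  with_seed(seed, {
    ws <- rnorm(n, params$mean_weight, params$sd_weight)
    while (any(ws <= 0.05)) {
      bad <- ws <= 0.05
      ws[bad] <- rnorm(sum(bad), params$mean_weight, params$sd_weight)
    }
    lapply(seq_len(n), function(i) {
      virtual_participant(sprintf("%s%03d", id_prefix, i), ws[i], ...)
    })
  })
}
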