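#' Apply the trial-exclusion rule
#'
#' Drops trials whose estimate is missing or below 10 (the outlier rule used
#' before any weight fitting). Order is preserved; dropped rows are returned
#' with the reason.
#'
#' @param records trial-record data.frame.
#' @return list with `kept` and `dropped` data.frames; `dropped` gains a
#'   `reason` column (`"missing_estimate"` or `"estimate_lt_10"`).
#' @export
clean_trials <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$estimate)] <- "missing_estimate"
  reason[!is.na(records$estimate) & records$estimate < 10] <- "estimate_lt_10"
  keep <- is.na(reason)
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

new_weight_fit <- function(w, noise_sd, loglik, n, tag) {
  aic <- 2 * 2 - 2 * loglik  # k = 2 free parameters: slope and noise SD
  structure(list(w = w, noise_sd = noise_sd, loglik = loglik, aic = aic,
                 n_trials = n, model_tag = tag),
            class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("<weight_fit> %s: w = %.4f, noise SD = %.3f, AIC = %.2f (n = %d)\n",
              x$model_tag, x$w, x$noise_sd, x$aic, x$n_trials))
  invisible(x)
}

fit_slope_ml <- function(est, pred, tag) {
  n <- length(est)
  if (n < 2) stop("need at least 2 trials to fit a weight")
  if (all(pred == 0)) stop("all regressor values are zero")
  w <- sum(est * pred) / sum(pred^2)
  res <- est - w * pred
  noise_sd <- sqrt(mean(res^2))  # ML (1/n) estimator, as AIC requires
  loglik <- if (noise_sd == 0) Inf else sum(dnorm(res, 0, noise_sd, log = TRUE))
  new_weight_fit(w, noise_sd, loglik, n, tag)
}

#' Fit the linear psychophysical model by maximum likelihood
#'
#' No-intercept Gaussian regression `Est(t) = w * DotNum(t) + eps`; the ML
#' slope is the closed form `sum(Est * Dot) / sum(Dot^2)` and the noise SD
#' is the ML (1/n) residual SD. Records should already be cleaned with
#' [clean_trials()].
#'
#' @param records trial-record data.frame (no missing estimates).
#' @return a `weight_fit` object with fields `w`, `noise_sd`, `loglik`,
#'   `aic`, `n_trials`, `model_tag`.
#' @export
fit_linear_weight <- function(records) {
  fit_slope_ml(records$estimate, records$dot_count, "linear")
}

#' Fit the log-linear psychophysical model by maximum likelihood
#'
#' As [fit_linear_weight()] with the natural-log-transformed regressor:
#' `Est(t) = w * log(DotNum(t)) + eps`.
#'
#' @inheritParams fit_linear_weight
#' @return a `weight_fit` object.
#' @export
fit_loglinear_weight <- function(records) {
  fit_slope_ml(records$estimate, log(records$dot_count), "loglinear")
}

#' Compare the linear and log-linear fits by AIC
#'
#' @param linear,loglinear `weight_fit` objects fitted to the same records.
#' @return list with `preferred` (`"linear"` or `"loglinear"`; ties go to
#'   linear) and `delta_aic` (loglinear minus linear; positive favors the
#'   linear model).
#' @export
compare_models <- function(linear, loglinear) {
  stopifnot(inherits(linear, "weight_fit"), inherits(loglinear, "weight_fit"),
            linear$model_tag == "linear", loglinear$model_tag == "loglinear")
  if (linear$n_trials != loglinear$n_trials) {
    stop("fits are based on different numbers of trials")
  }
  delta <- loglinear$aic - linear$aic
  list(preferred = if (linear$aic <= loglinear$aic) "linear" else "loglinear",
       delta_aic = delta)
}

#' Additional reward from mean absolute estimation error
#'
#' Stepwise payment rule: average absolute error below 5, 10, 15, 20, or 25
#' counts earns 1000, 800, 600, 400, or 200 JPY; larger errors earn 0. An
#' error of exactly 25 falls on neither strict bound and is mapped to the
#' 200-JPY step (the zero step requires error strictly above 25).
#'
#' @param mean_abs_error non-negative mean absolute error in counts.
#' @return reward in JPY.
#' @export
compute_reward <- function(mean_abs_error) {
  if (any(mean_abs_error < 0)) stop("mean_abs_error must be non-negative")
  vapply(mean_abs_error, function(e) {
    if (e < 5) 1000 else if (e < 10) 800 else if (e < 15) 600
    else if (e < 20) 400 else if (e <= 25) 200 else 0
  }, numeric(1))
}

#' Fit weights for every participant-phase cell of a trial table
#'
#' Applies [clean_trials()] then fits the requested model(s) per
#' (participant, phase).
#'
#' @param records trial-record data.frame.
#' @param model `"linear"`, `"loglinear"`, or `"both"`.
#' @return data.frame with columns `participant_id`, `phase`, `model`, `w`,
#'   `noise_sd`, `loglik`, `aic`, `n`.
#' @export
fit_weights_table <- function(records, model = c("both", "linear", "loglinear")) {
  model <- match.arg(model)
  tags <- if (model == "both") c("linear", "loglinear") else model
  kept <- clean_trials(records)$kept
  cells <- unique(kept[c("participant_id", "phase")])
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- kept[kept$participant_id == cells$participant_id[r] &
                kept$phase == cells$phase[r], , drop = FALSE]
    if (nrow(sub) < 2) next
    for (tag in tags) {
      fit <- if (tag == "linear") fit_linear_weight(sub)
             else fit_loglinear_weight(sub)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = cells$participant_id[r], phase = cells$phase[r],
        model = tag, w = fit$w, noise_sd = fit$noise_sd,
        loglik = fit$loglik, aic = fit$aic, n = fit$n_trials)
    }
  }
  do.call(rbind, rows)
}
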