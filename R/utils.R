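#' @useDynLib dyadnorm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var cor dnorm pnorm qnorm quantile
#'   t.test aov p.adjust complete.cases
#' @importFrom utils read.csv write.csv
NULL

#' Round half away from zero
#'
#' Deterministic rounding used everywhere an estimate is discretized:
#' ties go away from zero (`round_half_away(30.5)` is 31), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Push a value onto a fixed-length most-recent-first lag buffer.
push_lag <- function(history, value) {
  c(value, history)[seq_along(history)]
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Standard split-R-hat: each chain is halved, and the ratio of pooled to
#' within-sequence variance is computed over the resulting sequences.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return scalar R-hat (NA if fewer than 4 draws per chain or zero variance).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  chain_means <- colMeans(splits)
  chain_vars <- apply(splits, 2, var)
  W <- mean(chain_vars)
  B <- nn * var(chain_means)
  if (W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size via lag-autocorrelation (Geyer initial positive)
ess_basic <- function(draws) {
  x <- as.numeric(draws)
  n <- length(x)
  if (n < 8 || sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
  rho_sum <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    rho_sum <- rho_sum + ac[k]
  }
  n / (1 + 2 * rho_sum)
}
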