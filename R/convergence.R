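#' Absolute weight difference within a pair, per phase
#'
#' @param pair character vector of two participant ids.
#' @param weights_by_phase data.frame with columns `participant_id`,
#'   `phase`, `w` (e.g. the linear rows of [fit_weights_table()]).
#' @return named numeric vector, one |delta w| per phase in which both
#'   members have a fit; errors if a member lacks a fit in a shared phase.
#' @export
abs_weight_diff <- function(pair, weights_by_phase) {
  stopifnot(length(pair) == 2)
  phases <- unique(weights_by_phase$phase)
  out <- vapply(phases, function(ph) {
    w <- vapply(pair, function(id) {
      hit <- weights_by_phase$participant_id == id &
             weights_by_phase$phase == ph
      if (!any(hit)) stop("no weight fit for ", id, " in phase ", ph)
      weights_by_phase$w[which(hit)[1]]
    }, numeric(1))
    abs(w[1] - w[2])
  }, numeric(1))
  names(out) <- phases
  out
}

#' Enumerate shuffled (non-partner) pairs
#'
#' All unordered pairs of ids excluding the real pairs: the null set used
#' to test whether pairwise weight convergence exceeds what task repetition
#' alone produces.
#'
#' @param ids character vector of distinct participant ids.
#' @param real_pairs 2-column matrix (or list of length-2 vectors) of real
#'   pair ids; may be empty.
#' @return 2-column character matrix of shuffled pairs.
#' @export
make_shuffled_pairs <- function(ids, real_pairs = NULL) {
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  real_keys <- character(0)
  if (!is.null(real_pairs) && length(real_pairs) > 0) {
    rp <- if (is.list(real_pairs)) do.call(rbind, real_pairs) else real_pairs
    real_keys <- key(rp[, 1], rp[, 2])
  }
  all_pairs <- t(utils::combn(sort(ids), 2))
  keep <- !(key(all_pairs[, 1], all_pairs[, 2]) %in% real_keys)
  all_pairs[keep, , drop = FALSE]
}

#' Ordering accuracy of a set of estimates
#'
#' Spearman rank correlation (average ranks for ties) between the estimates
#' and the true dot counts: 1 for perfectly order-preserving estimation
#' regardless of numeric bias.
#'
#' @param records trial-record data.frame with at least 5 non-missing
#'   estimates.
#' @return scalar rank correlation; `NA` with a warning when the estimates
#'   are constant.
#' @export
ordering_accuracy <- function(records) {
  ok <- !is.na(records$estimate)
  est <- records$estimate[ok]
  dots <- records$dot_count[ok]
  if (length(est) < 5) stop("need at least 5 trials")
  if (sd(est) == 0) {
    warning("constant estimates; ordering accuracy undefined")
    return(NA_real_)
  }
  cor(est, dots, method = "spearman")
}

#' Routine effect-size statistics
#'
#' Two-tailed paired, Welch, and one-sample t tests with Cohen's d
#' (paired: mean difference over SD of differences; Welch: mean difference
#' over the pooled SD; one-sample: mean shift over the SD).
#'
#' @param x,y numeric vectors (`y` unused for the one-sample design).
#' @param design `"paired"`, `"welch"`, or `"one_sample"`.
#' @param mu null value for the one-sample design.
#' @return list with `t`, `df`, `p`, `cohens_d`, `design`.
#' @export
effect_stats <- function(x, y = NULL, design = c("paired", "welch",
                                                 "one_sample"), mu = 0) {
  design <- match.arg(design)
  if (length(x) < 2) stop("need at least 2 observations")
  if (design == "paired") {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (sd(d) == 0) {  # degenerate: identical pairs, no variance to test
      return(list(t = 0, df = length(x) - 1, p = 1, cohens_d = 0,
                  design = design))
    }
    tt <- t.test(x, y, paired = TRUE)
    cd <- mean(d) / sd(d)
  } else if (design == "welch") {
    tt <- t.test(x, y, var.equal = FALSE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    cd <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  } else {
    tt <- t.test(x, mu = mu)
    cd <- if (sd(x) == 0) 0 else (mean(x) - mu) / sd(x)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = cd, design = design)
}

#' Two-way between-participants ANOVA with partial eta squared
#'
#' @param values numeric outcome.
#' @param factor1,factor2 factors (coerced) of the 2 x 2 design.
#' @return data.frame with one row per effect (`factor1`, `factor2`,
#'   `interaction`): `F`, `df1`, `df2`, `eta_p2`.
#' @export
anova_2x2 <- function(values, factor1, factor2) {
  f1 <- factor(factor1)
  f2 <- factor(factor2)
  fit <- aov(values ~ f1 * f2)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  Fs <- tab[["F value"]]
  resid_row <- nrow(tab)
  effects <- c("factor1", "factor2", "interaction")
  data.frame(effect = effects,
             F = Fs[1:3],
             df1 = df[1:3],
             df2 = rep(df[resid_row], 3),
             eta_p2 = ss[1:3] / (ss[1:3] + ss[resid_row]))
}

#' Holm-Bonferroni adjustment across a declared family of p values
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values (never below the raw values).
#' @export
holm_adjust <- function(p) {
  p.adjust(p, method = "holm")
}
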