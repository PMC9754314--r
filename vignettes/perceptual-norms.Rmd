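---
title: "Modeling the emergence of perceptual norms in dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the emergence of perceptual norms in dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadnorm)
```

## The scientific problem

When two people repeatedly judge the same stimuli and see each other's
answers, their overt responses converge. The deeper question this package
addresses is whether the *covert generative function* behind those
responses — the psychophysical mapping from stimulus magnitude to
judgment — also converges and stabilizes, because only a shared generative
model lets people agree on targets they have never seen together. The
package implements the full computational pipeline for studying this in a
dot-number estimation task: virtual experiments, psychophysical weight
fitting, a Bayesian stability index, programmed interaction partners, and
a time-varying decomposition of social influence.

## The psychophysical model

A participant's estimate on trial $t$ is modeled linearly with no
intercept,

$$\mathrm{Est}_i(t) = w_i \times \mathrm{DotNum}(t) + \varepsilon,$$

where the estimation weight $w_i$ captures under- ($w<1$) or
over-estimation. `fit_linear_weight()` computes the ML slope in closed
form, $\hat w = \sum \mathrm{Est}\cdot d / \sum d^2$, with the ML ($1/n$)
residual SD so that the AIC ($k = 2$: slope and noise SD) is
likelihood-consistent. A log-linear variant (`fit_loglinear_weight()`,
natural log) is provided for the model comparison; on linear-world data
the linear model wins by AIC, and ties are reported as linear by
convention. Estimates that are missing or below 10 are excluded before
any fit (`clean_trials()`).

## The stability index

Stability of the generative function within a person is measured by a
hierarchical local-level state-space model:

$$w_i(t) \sim N(\mu_i(t), \sigma_{obs,i}), \qquad
  \mu_i(t) \sim N(\mu_i(t-1), \sigma_{\mu,i}),$$

with the per-participant SDs drawn from group-level normal distributions.
The system-noise SD $\sigma_{\mu,i}$ — how much the latent weight itself
wanders from trial to trial — is the stability index; smaller means a
more reliable generative function. `fit_stability()` reports its
posterior mean, central 95% interval, split R-hat and a crude effective
sample size, and `delta_sigma()` gives the post-minus-pre contrast
(negative = stabilization).

Numerical choices, all configurable through `mcmc_config()`:

* The nominally unbounded uniform priors are truncated to proper ranges:
  $[0, 5]$ for every SD and $[-5, 5]$ for group means. Weights live near
  1, so these bounds carry no material information.
* Group-level normals on SDs are truncated at 0, the only reading
  consistent with $\sigma \ge 0$.
* $\mu_i(1) \sim N(w_{obs}(1), 0.5)$ — the first-trial prior is not
  pinned down by the model statement; anchoring at the first observation
  with a wide SD is neutral.
* The sampler is Gibbs with forward-filtering backward-sampling for the
  latent paths and log-scale Metropolis steps for the SDs. The SD updates
  target the *marginal* Kalman likelihood (latent path integrated out),
  which removes the strong path–SD coupling that otherwise slows mixing;
  the path is drawn only on recorded iterations.
* Defaults are 4 chains, 500 burn-in iterations and 1000 kept draws per
  chain. With a single participant the group layer is dropped
  (uniform priors).
* Fits with any split R-hat above 1.05 warn and are flagged
  `reliable = FALSE`.

The likelihood has two independent routes
(`local_level_loglik(method = "kalman")` and `"direct"`, a dense
multivariate-normal evaluation); the test suite holds them to $10^{-6}$
agreement.

## Computer partners

Two programmed agents reproduce the interaction manipulations:

* The **Asch-type** partner is unresponsive:
  $\mathrm{Est}_p(t) = \mathrm{round}(0.61 \times d) + \eta$ with $\eta$
  uniform on $\{-2,\dots,2\}$ (1.21 for the overestimator). Noise is
  added *after* rounding the deterministic part, so estimates are
  integers without re-rounding; the original order of noise and rounding
  is ambiguous, and this choice keeps the support exactly
  $\mathrm{round}(w d) \pm 2$.
* The **Sherif-type** partner reciprocates through a lag-5 affine
  recurrence
  $w_p(t) = 0.61 + \sum_j a_j w_p(t-j) + \sum_j b_j w_i(t-j)$
  with the fitted coefficients
  $a = (0.091, 0.044, 0.037, 0.032, 0.025)$,
  $b = (0.066, 0.014, 0.001, -0.015, -0.011)$. The intercept 0.61 is
  numerically unrelated to the built-in bias. Since $\sum a = 0.229 < 1$
  the recurrence is a contraction: against a participant holding
  $w = 0.91$ it converges to
  $(0.61 + 0.055 \times 0.91)/(1 - 0.229) \approx 0.8561$.

Warm-up: the first five trials lack lags, so both buffers are
pre-filled — the agent's own with its built-in weight, the participant's
with a reference pre-interaction weight (0.91). This reproduces the
programmed initial bias while letting reciprocity act from trial 1. The
counterpart's implied weight on a trial is `estimate / dot_count`; the
recurrence needs weights but only estimates are observable.

For the overestimating Sherif partner the recurrence intercept was never
published. Both defensible conventions are implemented behind
`intercept_mode`: `"history"` (default) keeps the fitted intercept and
only moves the warm-start buffers to 1.21, which makes the agent approach
the participant rapidly from above; `"rescale"` recomputes the intercept
so the warm-start fixed point is exactly 1.21. No claim is made about
which matches the original implementation.

## The synthetic world

`simulate_experiment()` generates complete virtual experiments with the
statistical structure the downstream models assume:

* Baseline weights are drawn from $N(0.915, 0.2033)$ — the observed
  Phase-1 mean, with the SD derived from the fact that the partners' 0.61
  bias sat 1.5 SD below that mean.
* Within a phase the latent weight follows a Gaussian random walk
  (default $\sigma_\mu = 0.01$ per trial) observed with noise (default
  $\sigma_{obs} = 0.05$); the integer estimate adds rounded Gaussian
  noise in counts (default SD 2, commensurate with the agents' $\eta$)
  and is floored at 1. These defaults are the package's own choice of a
  realistic regime — weight drift that is visible but small relative to
  between-person spread — and are not revisited per analysis.
* During interaction the participant uses the same lag-5 reciprocating
  recurrence as the Sherif agent (default coefficients = the fitted
  $a_j, b_j$), with intercept $c_i = \mu_{entry}(1 - \sum a - \sum b)$ so
  that the participant's own entry weight is the fixed point when the
  partner matches it. Zero coefficients and zero noise reduce exactly to
  the solo dynamics.
* The latent weight is carried across phases, so interaction
  after-effects persist into post phases — the property the pre/post
  analyses measure.
* Schedules: lab 16/144/16 trials over magnitudes 25–55 step 2 (solo
  phases contain each magnitude exactly once; the 144-trial phase is nine
  repetitions of the set, a choice the trial count alone does not force);
  scanner and online designs use 25–58 step 3 with 24-trial solo and
  48-trial interaction phases. 24/48-trial phases repeat each of the 12
  magnitudes equally by default (`balanced = FALSE` samples uniformly
  instead — whether the original design balanced repetitions is not
  stated).

What a green test does *not* establish: the generator produces idealized
Gaussian random walks and exactly-specified reciprocity; real data add
response quantization quirks, lapses, attention drift, and model
misspecification that none of the recovery tests exercise. One sharp
edge worth knowing: with all noise off, weights whose product with every
(odd) lab magnitude lands exactly on .5 (i.e. $w \in \{0.5, 1.5\}$) have
all rounding errors aligned by the half-away-from-zero convention, and
the refit is biased by about $+0.012$ — any weight off that degenerate
set recovers to well under 0.01.

## Time-varying decomposition of social influence

During interaction a participant's weight is decomposed as

$$\mathrm{Est}_i(t) = (\mathrm{Baseline}
  + \mathrm{Coef}_{Atyp}(t)\,\mathrm{Atyp}(t-1)
  + \mathrm{Coef}_{Sim}(t)\,\mathrm{Sim}(t-1))
  \times \mathrm{DotNum}(t) + \varepsilon,$$

where atypicality
$\mathrm{Atyp} = 1 - \mathrm{Est}_p/(0.91\,d)$ is a nuisance controlling
for the partner's built-in bias and similarity
$\mathrm{Sim} = \pi/2 - \tan^{-1}(|\mathrm{Est}_i - \mathrm{Est}_p| /
|(w_i^{pre} - w_p^{pre})\,d|) \in (0, \pi/2]$ measures closeness relative
to the pre-interaction gap. A negative $\mathrm{Coef}_{Sim}$ means the
participant responds to preceding closeness by moving further toward an
underestimating partner. When the pre-interaction weights coincide the
$\mathrm{Sim}$ denominator vanishes; the continuous limits (0 for a
positive numerator, $\pi/2$ for zero) are returned rather than NaN.

Each time-varying coefficient follows a local linear trend
($\mathrm{Coef}(t) \sim N(\mathrm{Coef}(t-1) + \gamma(t-1), \sigma)$,
$\gamma(t) \sim N(\gamma(t-1), \sigma_\gamma)$); Baseline is static with
prior $N(w_i^{pre}, 0.2)$. Initial coefficient and trend states have
$N(0, 0.2)$ priors; trend scales are uniform on $(0, 2]$ and the residual
SD on $(0, 25]$ counts (the unbounded originals made proper). Regressors
enter unscaled; z-scoring was reported only for the neuroimaging GLMs.
Defaults reproduce the reported sampler: 4 chains of 20,000 iterations,
half discarded, thinned by 50.

Model comparison uses WAIC over the full model and seven reductions
(each subset of {Baseline, Atyp, Sim}; a model without a free Baseline
pins it at $w_i^{pre}$, which also defines the otherwise-unspecified Null
model). Two deliberate choices:

* The pointwise log-likelihood entering WAIC is the **one-step-ahead
  marginal predictive** $p(y_t \mid y_{1:t-1}, \theta)$ from the Kalman
  filter, not the density conditional on the sampled states. Conditional
  likelihoods let the flexible models' states absorb residual noise, and
  WAIC then *rewards* overfitting (in a zero-effect world the full model
  "beats" a correct reduced model by dozens of WAIC units); the marginal
  form restores the intended parsimony behavior.
* The per-participant "mean similarity coefficient" is the across-trial
  mean of the posterior means (equivalently the posterior mean of the
  per-draw trial average, which is what is stored so an interval is
  available); the reduction order was not specified.

`posterior_predictive_check()` correlates observed estimates with
predictions from the posterior-mean states. `simulate_decomposition_session()`
generates sessions from this model (against either agent) for recovery
experiments; it emits real-valued estimates by default so recovery is not
confounded with discretization.

A calibration note: at the 48-trial session length with a near-constant
similarity regressor, the split between Baseline and
$\mathrm{Coef}_{Sim}$ is weakly identified. The estimator of the mean
similarity coefficient is unbiased (long-run mean $-0.074$ for truth
$-0.06$, per-session SD $\approx 0.05$), and its *sign* is recovered in
over 90% of sessions, but roughly a quarter of per-session posterior
means fall just outside $[-0.12, 0]$. Tests assert the aggregate and the
sign property rather than pretending per-session precision the design
cannot deliver.

## Pair-level convergence analyses

`make_shuffled_pairs()` enumerates all non-partner pairings (42
participants with 21 real pairs give 840, hence the paired-\(t\) df of
839); `abs_weight_diff()` computes within-pair weight gaps per phase;
`ordering_accuracy()` is the Spearman rank correlation between estimates
and true counts (average ranks for ties — the original metric is not
spelled out, and the robust MM-estimator correlations are not
reproduced); `effect_stats()`/`anova_2x2()`/`holm_adjust()` provide the
routine statistics (the 216-participant 2×2 design with cells
49/56/60/51 yields the denominator df of 212). Identical paired samples
return $t = 0$, $d = 0$, $p = 1$ by convention rather than 0/0.

## Known limitations

* The samplers are purpose-built for these two model families, not a
  general PPL; diagnostics are split R-hat and a lag-autocorrelation ESS.
* WAIC values are not comparable with implementations that use
  conditional-on-states likelihoods (see above).
* The reciprocating-participant generator is the model family the
  inference assumes; it cannot falsify that family.
* Neuroimaging analyses that consumed these regressors are out of scope.
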