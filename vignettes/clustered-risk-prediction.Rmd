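---
title: "Risk prediction on clustered binary data: models, adjustments, and the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk prediction on clustered binary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustpred)
```

## The problem

Multicentre studies produce clustered binary outcomes: patients within a
centre are more alike than patients across centres even after conditioning
on their own covariates. Two further complications are routinely
overlooked when such data are used to *develop a risk model* rather than to
estimate an exposure effect:

* **Confounding by cluster (CBC).** The distribution of a predictor (the
  "exposure" `r`) varies across clusters, and that variation is associated
  with the clusters' outcome levels. In random-effects language, the
  random intercepts are correlated with the cluster mean of the exposure.
* **Informative cluster size (ICS).** The number of members per cluster is
  associated with the outcome given the covariates — e.g. high-volume
  centres with better outcomes. In random-effects language, the random
  intercepts are correlated with cluster size.

`clustpred` implements the full pipeline for studying and handling these
complications in prediction: a data generator with explicit CBC/ICS
mechanisms, cluster-specific and marginal fitters with the recommended
adjustments, conditional and marginal prediction engines,
predictive-performance metrics, diagnostics, and a study runner.

## Models

The cluster-specific model is the random-intercept logistic GLMM

$$\operatorname{logit} P(Y_{ij}=1 \mid x_{ij}, u_i) = \alpha_{CS} + u_i + x_{ij}^\top\beta_{CS},
\qquad u_i \sim N(0, \sigma_u^2),$$

fitted by maximum likelihood with adaptive Gauss–Hermite quadrature
(`fit_glmm()`, 21 nodes by default, delegated to `lme4::glmer`). The
degree of clustering is summarised by the latent-scale intra-cluster
correlation $ICC = \sigma_u^2 / (\pi^2/3 + \sigma_u^2)$
(`variance_to_icc()`). Cluster effects are recovered as empirical Bayes
posterior modes (`empirical_bayes()`), which shrink toward zero as a
cluster carries less information.

The marginal (population-average) model
$\operatorname{logit} P(Y_{ij}=1 \mid x_{ij}) = \alpha_M + x_{ij}^\top\beta_M$
is fitted by generalised estimating equations. `fit_gee()` implements the
exchangeable working correlation with the moment estimator of the
correlation parameter, a closed-form compound-symmetry working inverse,
scale fixed at 1, and robust sandwich variances; `fit_iee()` is the
independence special case (pooled ML point estimates, cluster-robust SEs
via `sandwich::vcovCL`).

`fit_cml()` maximises the conditional likelihood given cluster event
totals. Conditioning removes *all* cluster-level information, so the CML
exposure coefficient is a CBC-immune reference for the within-cluster
effect. The conditional likelihood denominator — an elementary symmetric
function over all within-cluster event configurations — is evaluated by
the standard two-term recurrence, carried out entirely in log space so
clusters of size 100 cannot overflow or underflow; tests verify the
recurrence against brute-force enumeration on small clusters and against
`survival::clogit`.

## Handling CBC and ICS in a prediction model

The adjustment strategy is declared through `model_spec()`:

* `adjustment = "rbar"` adds the cluster mean of the exposure
  $\bar r_i$ (CBC). Either parameterisation — raw `r` plus `rbar`, or the
  within/between decomposition $(r - \bar r_i,\ \bar r_i)$ — spans the
  same column space and yields identical fitted probabilities; the
  decomposition makes the within-cluster effect $\gamma_W$ directly
  readable and comparable to CML.
* `adjustment = "size"` adds $g(N_i)$ (ICS), with `g` one of identity,
  log, quadratic ($N, N^2$) or quantile-based categories for suspected
  non-linear volume–outcome relationships.
* `adjustment = "both"` adds both.

Both adjustments are cluster-level covariates: they explain part of the
between-cluster variance, which is exactly why they improve *marginal*
predictions (the predictions available for members of clusters outside
the development sample). Conditional predictions already carry the
cluster's estimated random effect, so they have little to gain.

## Predictions

From a GLMM fit:

* `predict_conditional(fit, newdata, mode = "known_u")` uses
  $\hat\alpha + \hat u_i + x^\top\hat\beta$, valid for members of training
  clusters; `mode = "u_zero"` sets $\hat u_i = 0$ (an "average-risk
  cluster"). Requesting `known_u` for an unseen cluster is an error that
  points to marginal prediction.
* `predict_marginal_glmm(fit, newdata, method = "integrate")` computes
  $p = \int \operatorname{logit}^{-1}(\eta + u)\,\phi(u; 0, \hat\sigma_u^2)\,du$
  by Gauss–Hermite quadrature (21 nodes, same scheme as the fitter).
  `method = "zeger"` instead scales the linear predictor by
  $(1 + c^2\hat\sigma_u^2)^{-1/2}$ with $c = 16\sqrt3/(15\pi)$ — the
  classical attenuation approximation, taken from the literature because
  the approximation is cited without the constant being printed where we
  encountered it. The two routes agree within 0.01 across the probability
  range (tested); the study runner defaults to exact integration.

From a GEE/IEE fit, `predict_from_marginal_fit()` applies the marginal
coefficients directly. For adjusted models evaluated on a lone individual
whose cluster-level information is unavailable, the explicit, opt-in
`fallback = "population"` substitutes the training-population mean of
$\bar r$ and the median cluster size, and records the substitution in the
prediction attributes.

Predicted probabilities never hit 0 or 1 exactly: linear predictors are
clamped at ±35, inside which `plogis` is strictly interior in double
precision.

## Performance measures

On a validation set, `performance_summary()` reports:

* **Calibration in the large** — intercept of a logistic model with the
  linear predictor as an offset (0 is perfect).
* **Calibration slope** — slope of the logistic regression of outcome on
  linear predictor (1 is perfect; < 1 indicates overfitting, > 1 a
  too-narrow prediction range).
* **C-statistic** — concordance over case–control pairs, ties counted ½,
  computed by the exactly equivalent midrank formulation.
* **RPMSE** — root mean squared error of predicted versus *true*
  probabilities, available in simulation only.
* **Brier score** — mean squared difference between outcome and
  prediction. One circulating definition takes a square root of this
  quantity; reported magnitudes in the applied literature correspond to
  the un-rooted convention, so both `brier` and `root_brier` are
  returned and the un-rooted value is the default report.

## The data generator

`generate_pair()` implements one study replicate:

1. Latent standard normals $(Z_u, Z_v, Z_w)$ per cluster with pairwise
   correlations $(\rho_{uv}, \rho_{uw}, \rho_{vw})$, factorised by the
   symmetric eigenvalue square root of the correlation matrix (accepts
   exactly singular but valid matrices; a non-PSD triple is an error
   naming the offending correlations).
2. Effects $u = \sigma_u Z_u$, $v = \sigma_v Z_v$, $w = \sigma_w Z_w$
   (standard-deviation scaling, so the stated variances hold exactly).
3. Cluster sizes $N_i \sim \text{Poisson}(\exp(a_0 + a_1 w_i) + 5)$.
   A zero draw is redrawn (its probability is negligible at the default
   settings, but a cluster must have at least one member; the +5 offset
   is part of the Poisson mean, not a hard minimum).
4. Covariates: three Normals with SD 0.3, 0.4, 0.5 and two binaries with
   prevalence 0.1, 0.2, independent of everything cluster-level.
5. Exposure $R_{ij} \sim \text{Bernoulli}(\operatorname{logit}^{-1}(\gamma_0 + v_i))$:
   $v$ (correlated with $u$ when $\rho_{uv} > 0$) moves the
   within-cluster exposure prevalence — the CBC mechanism.
6. Outcomes from the random-intercept model
   $\eta_{ij} = \beta_0 + (x_{ij}, r_{ij})^\top\beta + u_i$, with the true
   $\eta$ and $p$ stored for later RPMSE computation.

The validation dataset reuses the *same* cluster effects (so conditional
predictions describe new members of existing clusters) with freshly drawn
sizes, covariates, exposures and outcomes. When ICS is off, validation
cluster sizes are drawn larger — Poisson with mean $\exp(\alpha)$,
$\alpha \sim N(5.7, 0.3^2)$, mean about 313 — so the performance measures
are computed precisely; when ICS is on they follow the training law,
keeping size informative in validation too.

### Scenario presets and defaults

`scenario_preset()` encodes the study conditions: 30 clusters;
$\sigma_u^2 = 0.82$ (ICC 0.2) or 0.37 (ICC 0.1); $a_0 = 4.5, a_1 = 1$
(mean size $\exp(4.5)+5 \approx 100$); $\gamma_0 = \operatorname{logit}(0.4)$
(exposure prevalence ≈ 40%); $\beta_0 = -1.5$ with all slopes 1. S1 turns
both auxiliary channels fully off ($\sigma_v^2 = \sigma_w^2 = 0$); S2 sets
$\sigma_v^2 = \sigma_u^2$, $\rho_{uv} = 0.7$; S3 sets
$\sigma_w^2 = \sigma_u^2/2$, $\rho_{uw} = 0.7$; S4 combines them with
$\rho_{vw} = 0$ (independent mechanisms) or $0.5$ (related). With
$\rho = 0.7$ the active channel linearly explains $\rho^2 \approx$ half of
the between-cluster variance. A supplementary small-sample variant
(`small_sample = TRUE`) uses 15 clusters of mean size 50 at 15% outcome
prevalence; the intercept achieving that prevalence is not part of the
preset's published parameters, so it is solved deterministically by
quadrature over the Gaussian part of the linear predictor plus enumeration
of the binary covariates (`solve_intercept_for_prevalence()`).

A note on calibration of the generator: at these parameters the marginal
outcome prevalence implied by the model is close to, but a little below,
40% (about 35–36% by quadrature under S1; member-weighted prevalence is
higher under ICS scenarios because large clusters are high-risk). The
parameters, not the prevalence, are the specification, so they are kept
exactly as stated.

### Seeding

`replicate_seeds(master_seed, n)` derives per-replicate seeds from one
master seed, so replicates are individually reproducible and a rerun of
any cell with the same master seed is bitwise identical. All
randomisation in the package flows through these seeds.

## Diagnostics

`cbc_diagnostic()` compares the exposure coefficient under CML, GLMM and
IEE. Without CBC, marginal estimates are attenuated toward zero relative
to cluster-specific ones; a marginal estimate *exceeding* the CML estimate
in magnitude is the distortion suggestive of CBC. The published form of
this comparison is informal, so the flag threshold is an explicit
implementation choice: the distortion must exceed half the larger of the
two standard errors (`margin_factor = 0.5`, configurable and reported).
`ics_test()` adds $g(N)$ to the GLMM and Wald-tests its coefficient
(joint chi-squared test when $g$ spans several columns).
`cluster_summaries()` provides the per-cluster table (size, event
proportion, exposure proportion) behind the usual exploratory plots.

## The study runner

`run_cell()` executes one (scenario × model × adjustment × prediction
type) cell: generate pair → fit on training → predict on validation →
evaluate, collecting per-replicate rows plus across-replicate means with
Monte-Carlo standard errors (`aggregate_results()`). Replicates whose fit
fails are excluded *and counted* — never silently averaged.
`internal_validation_bootstrap()` performs optimism correction on a single
dataset; it resamples clusters, not members, because members of a cluster
are not exchangeable across clusters and the cluster is the independent
sampling unit.

## Numerical choices

* GLMM integration: adaptive Gauss–Hermite, 21 nodes (Laplace available
  via `nAGQ = 1` for quick exploratory fits). Standard errors are from
  the observed information at the ML solution; REML-type corrections are
  not implemented because predictions, not variance-component inference,
  are the target.
* GEE: alternating coefficient/correlation updates to joint tolerance
  1e-6, max 100 iterations; the exchangeable correlation estimate is
  clamped to [−0.05, 0.95] during iteration.
* CML: BFGS on the log conditional likelihood (relative tolerance 1e-12)
  with observed-information standard errors; log-space recurrence for the
  denominators.
* Separation: a coefficient exceeding 15 on the standardised design
  triggers an explicit error naming the column.
* Calibration models: `stats::glm` with tightened IRLS tolerance (1e-10).
* C-statistic ties: counted ½ (midranks).

## Problem sizes used in the shipped checks

The test suite and the acceptance script reproduce the study at desk
scale: 100 replicates per scenario cell (the headline study used 500) at
the full data size per replicate (30 clusters × ~100 members training,
~313 per cluster validation), with Monte-Carlo standard errors reported
alongside every across-replicate mean. Large one-shot checks (parameter
recovery, mechanism correlations) use between 10^4 and 6 × 10^4 clusters.
Property tests that need many refits (e.g. the type-I error of the ICS
test) run at reduced cluster sizes and with the Laplace approximation;
checks compared against published values always use the full quadrature
default.

## What the generator does and does not emulate

The generator reproduces the mechanisms that matter for CBC/ICS —
cluster-level confounding through a shared latent normal triple,
size-outcome coupling, shared effects between training and validation.
It does not emulate features of real multicentre data such as non-normal
random effects, covariate distributions that differ across clusters,
missing data, or more than one level of clustering. Tests passing on
synthetic data therefore demonstrate correctness of the methods under the
stated mechanisms, not robustness to those further departures; the
Non-goals above are deliberate scope boundaries, not oversights.

## Known limitations

* Random slopes, weighted-GEE estimation under ICS, and joint
  outcome/cluster-size models are out of scope.
* The categorical cluster-size transform computes its quantile bins from
  the data it is given; predictions on new data recompute bins from the
  new data, so the categorical transform is best reserved for exploratory
  ICS testing rather than transportable prediction models.
* CML standard errors use the observed information from the BFGS Hessian;
  for very sparse clusters a profile-likelihood interval would be more
  accurate.
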