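---
title: "Methods: Bayesian geostatistical modelling of childhood stunting"
author: "geostunt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geostatistical modelling of childhood stunting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`geostunt` analyses binary stunting outcomes of children nested in
geo-located survey clusters, of the kind collected by Demographic and
Health Surveys (DHS). For child $i$ in cluster $j$:

$$
y_{ij} \sim \mathrm{Bernoulli}(p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \beta_0 + \sum_q \beta_q X_{iq}
  + \sum_l \gamma_l Z_{il} + s_j + u_j .
$$

$X_{iq}$ are continuous covariates (age in months, birth weight in kg,
preceding birth interval in months), centered on their observed means so
that odds ratios are per-unit effects around a typical child. $Z_{il}$
are reference-omitted indicators of the categorical covariates; the
reference of each is the category with the least stunting risk, whose
coefficient is pinned to zero (corner constraint). Two random-effect
layers absorb cluster-level variation:

* $u_j \sim N(0, \sigma_u^2)$ — exchangeable (spatially unstructured)
  heterogeneity;
* $s = (s_1, \dots, s_J) \sim \mathrm{MVN}(0, \Sigma)$ with the isotropic
  exponential covariance $\Sigma_{jk} = \sigma_s^2 e^{-\phi d_{jk}}$,
  where $d_{jk}$ is the inter-cluster distance in kilometres — the
  spatially structured field whose exponentiated surface is the
  *residual odds ratio*: stunting risk not explained by the covariates.

Model 1 omits the field ($s$, $\sigma_s$, $\phi$ are absent from its
state); Model 2 carries both layers. Fitting both and comparing them with
the pseudo marginal likelihood (PsML) quantifies how much genuinely
spatial signal the covariates leave behind.

### Priors

Coefficients get hierarchical normal priors $\beta_q \sim N(0,
\sigma_\beta^2)$, $\gamma_l \sim N(0, \sigma_\gamma^2)$ with uniform
standard deviations $\sigma_\beta, \sigma_\gamma \sim U(0, 10)$; one
$\sigma_\beta$ is shared across the continuous coefficients and one
$\sigma_\gamma$ across all categorical contrasts (whether the original
analysis shared or separated them is not documented; sharing is the
simpler hierarchical reading and is a package choice). The intercept is
given an independent vague $N(0, 10^2)$ — hierarchical shrinkage of the
baseline prevalence towards zero would be meaningless. $\sigma_s,
\sigma_u \sim U(0, 10)$ and $\phi \sim U(0, 1)$ per km, so the effective
range $3/\phi$ of the field spans everything from 3 km to (effectively)
unbounded; distances are computed in kilometres precisely so that this
unit-less prior is interpretable at country scale. All uniform uppers and
the $\phi$ support are configurable through `prior_spec()`.

### Missing covariates

Missingness is treated as ignorable (missing completely at random), which
matches how the synthetic generator masks cells, and missing cells are
sampled within the chain rather than dropped. Sub-models:
$X_i \sim N(\mu_X, \sigma_X^2)$ for continuous covariates, and for a
categorical covariate a multinomial with softmax probabilities
$\pi_k = e^{\eta_k} / \sum_m e^{\eta_m}$, $\eta_1 = 0$. The sub-model
means take vague normals specified in the (mean, precision) convention
with precision $10^{-3}$, i.e. variance 1000; their SDs take $U(0, 10)$.
One reading issue was settled as a design choice: the category linear
predictors are shared across children ($\eta_k$, not $\eta_{ik}$) — a
per-child latent would make the sub-model an unidentifiable
overdispersed multinomial given a single draw per child.

## Sampling

The sampler is Metropolis-within-Gibbs, designed for this posterior
rather than delegated to a generic engine:

* **Coefficients** — univariate adaptive random-walk Metropolis with
  Robbins–Monro tuning of each log step size towards 0.44 acceptance,
  *during burn-in only*; steps are frozen afterwards so that the retained
  chain satisfies detailed balance exactly.
* **Spatial field** — elliptical slice sampling under the MVN prior.
  This is tuning-free, always moves, and needs only likelihood
  evaluations; the Cholesky factor of the correlation matrix is cached
  and refreshed only when $\phi$ moves.
* **$\sigma_s$, $\phi$, $\sigma_u$, $\sigma_\beta$, $\sigma_\gamma$** —
  univariate Metropolis on log (SDs) or logit ($\phi$) scales with the
  appropriate Jacobians; proposals outside the uniform supports are
  rejected, so draws never leave the prior support.
* **$u$** — a joint proposal accepted or rejected per cluster (each
  $u_j$'s full conditional touches only its own children), vectorised.
* **Imputation** — missing continuous cells are proposed from their
  sub-model $N(\mu_X, \sigma_X^2)$, so the Metropolis ratio reduces to
  the outcome-likelihood ratio; missing categorical cells are redrawn
  exactly from their discrete full conditional
  $\propto \pi_k \cdot \mathrm{Bernoulli}(y_i \mid \eta_i(k))$ (a Gibbs
  step). Sub-model parameters are refreshed by Metropolis against their
  densities and priors.

A correctness cross-check in the test-suite fits the intercept +
exchangeable-effects reduction of the model with an independent Gibbs
engine (JAGS) and compares posterior means and quantiles; a second check
verifies the intercept-only posterior covers a known 38% prevalence.

### Numerical choices

* Distances: haversine on lon/lat input (radius 6371.0088 km), Euclidean
  for planar kilometre input.
* A relative diagonal jitter of $10^{-10}$ keeps correlation matrices
  positive definite at near-duplicate locations; the same jitter enters
  the kriging system, so interpolation at a data location is exact to
  about $10^{-8}$ rather than machine precision.
* The Bernoulli log-likelihood uses a piecewise-stable
  $\log(1 + e^x)$, so proposals with extreme linear predictors are
  handled without overflow.
* Centering uses observed-case means computed once before sampling, not
  per-iteration means over imputed values, for reproducibility.
* The linear predictor is maintained incrementally across updates and
  recomputed from scratch every 1000 iterations to cancel drift.
* Ties in the categorical-imputation Gumbel-argmax draw are broken by
  the RNG; all randomness flows from the single chain seed.

### Run lengths

The protocol default is a single chain of 40,000 iterations with 20,000
burn-in. The package's own simulations (tests and the acceptance script)
use a desk-scale profile — typically 2,500–10,000 iterations on surveys
of 40–100 clusters and 400–3,000 children — which the R-hat/ESS
diagnostics show is adequate for the regression coefficients at those
sizes. Multi-chain fitting and split R-hat/ESS reporting are additions
over the original single-chain, visual-inspection protocol; fits warn
when any top-level R-hat exceeds 1.1.

## Model checking

Per observation, with $T$ retained draws and
$L_{it} = \Pr(y_i \mid \theta_t)$:

* **CPO** (conditional predictive ordinate), the leave-one-out
  predictive density, via the harmonic-mean identity
  $\mathrm{CPO}_i = (T^{-1} \sum_t L_{it}^{-1})^{-1}$. Brute-force
  leave-one-out refitting on toy data pins the estimator to within 5%.
  Entries whose denominator is dominated more than 50% by one draw are
  flagged unstable.
* **B-p-value**, the replicate-match probability
  $\Pr(y^{rep}_i = y_i \mid y)$, computed analytically as
  $T^{-1} \sum_t L_{it}$ (the Rao-Blackwellised form; simulating
  replicates would only add noise). By Jensen's inequality
  $\mathrm{CPO}_i \le \text{B-p}_i$ always, with equality for a
  point-mass posterior. The literature sometimes labels these values
  cross-validatory; the formula implemented (and printed in the source
  study) is posterior-predictive.
* **PsML** $= \sum_i \log \mathrm{CPO}_i$, a pseudo Bayes factor;
  larger is better. The scaled-CPO screen divides by the maximum and
  flags entries below 0.001 as outliers.

Two practical notes on these tools, learned the quantitative way while
validating them. First, the harmonic-mean estimator converges
impractically slowly when the posterior has heavy tails relative to an
observation's likelihood — on very small data under fully vague priors
the agreement with brute-force leave-one-out can take millions of draws;
the package's own oracle check therefore uses moderately informative
priors (identically in both routes). Second, the PsML advantage of the
spatial model is intrinsically small per observation (a few thousandths
of a log unit per child at survey scale): it is only detectable when the
cluster geometry actually carries spatial information, i.e. when
inter-cluster spacing is well inside the field's effective range
$3/\phi$ and cluster effects are not already pinned down by many
children per cluster. Sparse clusters with large samples each make
Model 1 and Model 2 practically indistinguishable by PsML — a property
of the statistic, not a defect of the sampler.

## Prediction

The field is interpolated to the centroids of a regular square lattice
(default 5 km) by simple kriging: per retained draw,
$\lambda_0 = \Sigma_{0i}\Sigma_{ij}^{-1}$ and $s_0 = \lambda_0 s$. The
published formula for the weights omits the inverse; $\Sigma_{0i}
\Sigma_{ij}^{-1}$ is the only reading under which $\lambda$ is a weight
matrix, and it is the GP conditional mean. Only the structured field $s$
is interpolated: the exchangeable $u_j$ is cluster-specific noise with no
spatial law to interpolate under (whether the original maps folded $u$
into the prediction cannot be determined from the text; predicting $s$
alone is the defensible choice and is flagged here). Cells are treated
independently — per-cell marginal summaries, no joint conditional
covariance — matching the per-location prediction the study describes;
an optional conditional-simulation mode adds per-cell conditional
variance as noise. The surface is reported as the posterior mean of
$e^{s_0}$ (residual odds ratio) and its SD on the same scale (SD of
$s_0$ is also returned). By default weights are recomputed every 10th
retained draw to bound cost; `draw_thin = 1` reproduces the
every-iteration scheme.

## The synthetic generator

`simulate_stunting_survey()` emulates the 2015 Rwanda survey that
motivated the model: 492 clusters placed uniformly in a Rwanda-sized
lon/lat box, 4–12 sampled children per cluster (mean ≈ 7.3, matching
3,593 children in 492 clusters), covariates drawn from the published
descriptive marginals, a marginal prevalence near 38%, true covariate
effects defaulting to the published adjusted odds ratios, and MCAR
masking that reproduces the observed missingness — notably ≈ 61% and
≈ 59% for exclusive breastfeeding and dietary diversity, which are only
measured for children under two. The spatial defaults
($\sigma_s = 0.8$, $\phi = 0.05$/km, $\sigma_u = 0.3$) were fixed once:
the source study does not report posterior estimates of its variance
components, and these give an effective range of 60 km and substantial
but not dominant cluster-level variation, which is what its residual
maps depict qualitatively.

What the generator deliberately does **not** emulate: the two-stage
household sampling design and survey weights, the DHS coordinate
displacement (absorbed in practice by the 5 km analysis grid),
anthropometric measurement and the height-for-age dichotomisation
(outcomes are generated directly as binary), and any
missing-not-at-random mechanism. Passing recovery tests on these data
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — not robustness to design effects or
informative missingness in real DHS data.

## Known limitations

* The harmonic-mean CPO estimator has infinite variance in adversarial
  cases; the dominance flag marks untrustworthy entries.
* Uniform cluster placement is a neutral stand-in for the DHS sampling
  frame; real cluster patterns are denser in cities.
* The exponential covariance has no alternative families (Matérn,
  spherical) and no anisotropy; $u_j$ plays the nugget's role at cluster
  level.
* $\sigma_s$ and $\phi$ are weakly identified in logistic models at
  moderate cluster counts; their chains mix slowly, which is why
  recovery checks target the regression coefficients.
* Crosstab odds ratios accept optional per-child weights, but no
  design-based variance estimation is provided.
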