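---
title: "Spatially varying mixture effects: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially varying mixture effects: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epidemiological mixture analysis asks how a *group* of correlated exposures —
for example several PCB congeners measured in house dust — jointly affects a
health outcome, and how much each component contributes. Weighted-quantile-sum
and Bayesian group-index models answer this with a single weighted index per
mixture. But the effect of a mixture need not be the same everywhere in a
study region: local policy, demography, or exposure sources can make it vary
over space. Estimating one global coefficient then biases the effect both up
and down in different places and can hide localized signals entirely.

`svcmix` fits a Bayesian spatially varying mixture model for case-control
data that lets every mixture's effect be a smooth spatial field while the
component importance weights stay global.

## Model

For subject $i$ at planar coordinates $s_i$, with binary outcome
$Y_i \sim \text{Bernoulli}(p_i)$:

$$
\log \frac{p_i}{1 - p_i} \;=\; \beta_{i0}
\;+\; \sum_{j=1}^{C} \beta_{ij} \sum_{k=1}^{C_j} \omega_{jk}\, q_{ijk}
\;+\; \sum_{b=1}^{B} \theta_b x_{ib},
$$

where $q_{ijk} \in \{0, \dots, Q-1\}$ is the quantile score of component $k$
of mixture $j$ (quartiles by default), $\omega_{jk}$ are importance weights
constrained to the simplex, $\beta_{ij}$ is the effect of mixture $j$ *at the
location of subject $i$*, $\beta_{i0}$ is a spatially varying intercept, and
$\theta_b$ are spatially constant adjustment-covariate effects.

Each spatial field (the intercept and one field per mixture) gets a mean-zero
Gaussian-process prior with Matern-3/2 correlation
$\rho(d) = (1 + d/\rho)\exp(-d/\rho)$ and covariance $\tau^{-1}\Omega$, where
$\Omega_{jk}$ is the correlation between subject locations $j$ and $k$. We
read the precision-style notation for this prior as covariance proportional
to the *correlation* matrix — the standard GP prior — since a covariance
proportional to $\Omega^{-1}$ would invert the distance-decay of dependence.

Priors: $\omega_j \sim \text{Dirichlet}(\alpha)$ with $\alpha = \mathbf 1$
(non-informative) by default; $\rho \sim \text{Uniform}(d_{\min}, d_{\max})$
over the observed inter-point distance range; each field scale
$\sigma_\beta \sim \text{Uniform}(0, 10)$ with $\tau = \sigma_\beta^{-2}$;
$\theta_b \sim N(0, \sigma_b^2)$ with $\sigma_b \sim \text{Uniform}(0, 10)$.
The intercept field receives the same prior family as the mixture fields with
its own scale (no explicit prior is stated for it in the source model), and a
single range $\rho$ is shared by all fields. The field-scale prior mirrors
the covariate-scale prior, which is the stated form; the field precisions
themselves have no stated prior.

### Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `q` | quantile bins per component | 4 | bins |
| `alpha` | Dirichlet concentration | 1 | — |
| `sigma_upper` | upper bound of the scale priors | 10 | logit scale |
| `rho_bounds` | support of the range prior | observed $d_{\min}, d_{\max}$ | coordinate units |
| `jitter` | diagonal nugget on $\Omega$ | $10^{-6}$ | correlation |
| `threshold` | exceedance significance level | 0.95 (alt. 0.90) | probability |

Coordinates are taken as planar; geographic projection is the caller's
responsibility. Quantile scores use in-sample breaks at the $Q-1$ interior
sample quantiles with right-closed intervals (ties share their interval's
score); no tie rule or quantile algorithm is prescribed by the model itself,
so this is a recorded package choice. Scores are invariant to strictly
increasing transforms of a component, which also makes the (unstated)
component means of the simulation design irrelevant.

## Posterior computation

The sampler is native (C++ via RcppArmadillo) rather than a generic Gibbs
program: with $n(C+1)$ latent field values, a generic one-site Gibbs sampler
is impractical at desk scale, and the target distribution — not any
particular sampler — is the model. Per sweep:

* **fields** — elliptical slice sampling under the exact MVN prior (no
  tuning parameters, always accepts within the slice);
* **weights** — adaptive random-walk Metropolis on the additive-log-ratio
  transform of each simplex with the Jacobian correction, targeting 0.234
  acceptance;
* **covariate effects** — adaptive scalar random walks targeting 0.44;
* **range $\rho$** — reflective random walk on its uniform support; the
  correlation Cholesky is recomputed only on range proposals, and sweeps
  alternate a *centered* update (fields fixed; prior ratio) with a
  *non-centered* one (whitened fields $v = L^{-1}f$ fixed; likelihood
  ratio). The interweaving matters: centered-only range updates mix an
  order of magnitude more slowly because the fields pin the range down;
* **scales** — reflective random walks on $(0, 10)$, again interweaving a
  centered update with a non-centered rescaling of the field.

Adaptation runs only during burn-in (batches of 50 sweeps with decaying step
adjustments), so retained draws come from a fixed kernel. Chains start
overdispersed: fields drawn from the prior at unit scale, weights from
Dirichlet($\alpha$), $\theta \sim N(0,1)$, $\rho$ uniform on its bounds. All
randomness flows through R's RNG, so a run is reproducible bit-for-bit from
its seed. Convergence is monitored with the Gelman-Rubin statistic on every
scalar parameter, flagged at the conventional 1.1.

Default run length is desk-scale — 2 chains of 2000 burn-in + 2000 retained
sweeps; production-scale runs (burn-in and retained draws of $10^5$ or more)
are a configuration change, not a code change.

### Grid prediction

Coefficient surfaces are kriged onto a regular grid (30 x 30 by default) by
*joint* conditional MVN draws — one draw of the whole grid field per retained
iteration, using that iteration's field values, range and precision — rather
than a posterior-mean plug-in. This propagates full posterior uncertainty
into the exceedance probabilities. Because consecutive MCMC iterations are
autocorrelated, the grid draws may be thinned (default: about 150 iterations
per chain) without losing exceedance resolution; the jitter nugget is added
to both correlation blocks, and a near-singular conditional covariance (for
cells coinciding with data sites) falls back to an eigenvalue-clamped factor
instead of failing. Exceedance probabilities count draws strictly above or
below zero; draws exactly at zero (a measure-zero event) count toward
neither direction.

## The synthetic-data generator

The generator reproduces the simulation design the model was validated
against, so every downstream module is testable without external data:

* locations uniform on the unit square (placement is not otherwise stated);
* six components per mixture from zero-mean, unit-variance multivariate
  normals with the two fixed correlation matrices (entries 0.1-0.3 among the
  first four components, the last two independent);
* true weights $\omega_1 = (0.30, 0.20, 0.20, 0.13, 0.10, 0.07)$ and
  $\omega_2 = (0.45, 0.15, 0.15, 0.15, 0.05, 0.05)$;
* effect surfaces: constant (mean 0 for the null scenario, mean 1 for the
  second mixture of two-mixture scenarios), one-dimensional vertical thirds
  with means 3 / 1.5 / 0 split at $x = 1/3, 2/3$, and radial decay from 3 at
  the center to 0 on the boundary. The radial profile's functional form is
  not stated; we use linear decay in distance from $(0.5, 0.5)$ reaching 0
  at $r = 0.5$ and clamped beyond, which makes the nested evaluation strata
  (true mean at least 2 / 1 / 0.25) concentric disks;
* per-location effects are the surface mean plus $N(0, 0.1^2)$ noise; the
  0.1 SD is stated only for the two-mixture class and extended to all
  scenarios for consistency;
* outcomes are Bernoulli with a globally calibrated intercept (bisection on
  $[-20, 20]$ to $10^{-8}$) giving an approximately 1:1 case:control ratio;
* no adjustment covariates (the validated design had none), and quartile
  scoring ($Q = 4$), matching the data-analysis convention since the
  simulation's own $Q$ is unstated;
* the number of subjects per dataset is likewise unstated; the package
  default is $n = 1000$, and every validation run states the $n$ it used.

Scenario presets are keyed by spatial pattern (`constant_null`, `one_dim`,
`radial`, `two_mix_one_dim`, `two_mix_radial`) rather than by opaque scenario
codes, because published labelings of the radial and one-dimensional variants
contradict each other between text and tables.

What the generator does *not* emulate: spatially correlated component
concentrations, covariate confounding, non-planar or irregular regions,
informative sampling of locations. Passing tests therefore demonstrate
correct recovery under the stated generative design — not robustness to the
many ways real exposure data deviate from it.

## Evaluation metrics

Per fitted dataset: coefficient MSE between the true mean surface at subject
locations and the posterior-mean field; weight-recovery MSE and absolute
error (both the mean and the median of the componentwise absolute errors are
reported, since both conventions appear in this literature; study-level
tables use the mean form); the proportion of significant grid cells
stratified by the spatial pattern (vertical thirds, nested radial disks, or
the whole region), counting elevated-only cells except for the null constant
surface where both directions count; and, for two-mixture fits, the Pearson
correlation between the two posterior-mean coefficient fields. Across
datasets the coefficient MSE is aggregated by the *median* and everything
else by the mean, following the summary convention of the validated design.

## Validation scale

The package's acceptance checks rerun the simulation study at a scale chosen
for a single CPU: three datasets per scenario at $n = 500$ with 2 chains x
(2000 + 2000) sweeps and range updates every other sweep for the spatial
profiles; one $n = 1000$ dataset per scenario with 1 chain x (1000 + 1000)
for weight recovery; `scripts/acceptance.R` uses two datasets per scenario at
$n = 500$ with 2 chains x (1500 + 1500). These sizes are the package's
choice of a reproducible desk-scale design; the qualitative targets (high
power in high-mean strata, low false-positive rates under the null, weight
MAE near the reported 0.06-0.10 band) are stable at this scale, while the
printed long-run values were produced with two orders of magnitude more
posterior draws.

## Known limitations

* Importance weights are global; only the mixture *effects* vary over space.
  Spatially varying weights would need a different constrained-field prior
  and are out of scope.
* There is no formal test for the presence of spatial variation; a truly
  global effect is simply estimated as a nearly flat field.
* No spatial random effect is included alongside the varying coefficients —
  simultaneous unstructured and structured spatial terms raise
  identifiability concerns.
* Only the Bernoulli-logit outcome is implemented; the linear predictor
  would carry over to other outcome families by a link change, but those
  paths are untested here.
* Dense Cholesky factorizations bound practical problem sizes to a few
  thousand subjects; no low-rank or sparse GP approximations are provided.
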