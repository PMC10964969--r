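# svcmix

Bayesian spatially varying mixture models for binary health outcomes.

## The problem

Mixture analysis estimates the joint effect of a *group* of correlated
exposures (e.g. PCB congeners, PAHs, or pesticide panels measured in house
dust) on a disease outcome, together with the relative importance of each
component. Standard group-index / weighted-quantile-sum models assume one
global mixture effect. When the effect truly varies across a study region —
because of local sources, policy, or demography — a global coefficient is
biased everywhere and can obscure localized associations entirely.

`svcmix` is for epidemiologists and spatial statisticians analyzing
case-control data with per-subject coordinates. It fits a logistic
group-index regression whose mixture coefficients (and intercept) are
Gaussian-process spatial fields:

```
logit(p_i) = beta_i0 + sum_j beta_ij * sum_k omega_jk q_ijk + sum_b theta_b x_ib
```

with quantile-scored components `q_ijk`, simplex importance weights
`omega_j ~ Dirichlet(alpha)`, Matern-3/2 spatial correlation
`(1 + d/rho) exp(-d/rho)` with a uniform prior on the range `rho` over the
observed inter-point distances, and Uniform(0, 10) priors on all scale
parameters. Inference is by multi-chain MCMC (elliptical slice sampling for
the latent fields, adaptive random-walk Metropolis with centered /
non-centered interweaving for the constrained scalars), with Gelman-Rubin
diagnostics, joint kriging of coefficient surfaces onto a regular grid, and
exceedance-probability significance maps (`P(beta > 0) > 0.95` flags an
elevated effect; odds ratios by exponentiating the coefficient draws).

A simulation toolkit generates case-control datasets with known spatial
effect surfaces (constant, one-dimensional bands, radial decay), fixed true
weights and component correlation structure, and scores fitted models
against the truth (coefficient MSE, weight MSE/MAE, significant-cell
proportions by stratum, inter-coefficient correlation). See the methods
vignette (`vignettes/svcmix-methods.Rmd`) for the full model, the sampler
design, and every recorded design choice.

## Worked example

Simulate one dataset whose mixture effect steps down across vertical thirds
of the unit square (true means 3 / 1.5 / 0), fit it, and map where the
effect is credibly elevated:

```r
library(svcmix)

sim <- simulate_scenario("one_dim", n = 500, D = 1, seed = 3)[[1]]
fit <- svcmix(sim$data, sim$design$mixtures,
              config = sampler_config(seed = 5, rho_every = 2))
fit
#> <svcmix_fit> 500 subjects, 1 mixture(s); 2 chain(s) x (2000 burn-in + 2000 retained, thin 1)
#>   max Gelman-Rubin: 1.086  (9/9 scalar parameters < 1.1)
#>   elapsed: 39.1s

grid <- predict_grid(fit, grid_size = 30, bbox = c(0, 1, 0, 1), thin = 20)
summary <- exceedance_summary(grid, threshold = 0.95)
significant_proportion_by_stratum(
  dplyr::filter(summary, field == "mix1"), "one_dim")
#> # A tibble: 3 × 3
#>   stratum n_cells proportion
#>   <chr>     <int>      <dbl>
#> 1 left        300      1
#> 2 middle      300      0.913
#> 3 right       300      0.297
```

The left third (true mean 3) is flagged elevated in every grid cell, the
middle third (true mean 1.5) in 91%, and the null right third in 30% —
the decreasing power profile the model is supposed to recover. The
estimated importance weights track the generating simplex
(0.30, 0.20, 0.20, 0.13, 0.10, 0.07):

```r
summarize_weights(fit)
#> # A tibble: 6 × 6
#>   mixture component   mean   lower upper  rank
#>   <chr>   <chr>      <dbl>   <dbl> <dbl> <int>
#> 1 mix1    mix1_c1   0.284  0.163   0.427     1
#> 2 mix1    mix1_c2   0.236  0.0956  0.358     3
#> 3 mix1    mix1_c3   0.244  0.126   0.363     2
#> 4 mix1    mix1_c4   0.0912 0.0144  0.197     5
#> 5 mix1    mix1_c5   0.106  0.0105  0.210     4
#> 6 mix1    mix1_c6   0.0380 0.00337 0.102     6
```

`tidy(fit)` / `glance(fit)` give broom-style parameter and fit summaries,
`autoplot(summary)` draws the coefficient surface with significance
markers, and `export_maps(summary, "grid.csv")` writes the map-ready CSV.
File-based pipeline stages (`cli_simulate`, `cli_fit`, `cli_predict`,
`cli_evaluate`, `cli_replicate`) and a thin shell wrapper
(`inst/scripts/svcmix`) chain the same steps on disk.

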