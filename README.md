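# crosslag

Simulation and unbiased estimation for cross-lagged biological time
series.

## The problem

Longitudinal studies in ecology and evolution routinely regress a
response `Y_t` (reproduction, a vital rate, group productivity) on a
same-step covariate `X_t` (growth, population size, group size) to
estimate the *contemporaneous effect* `b`. But in many biological systems
the covariate depends on the response of the previous step — a
**cross-lag**: offspring recruit into next year's group, this year's
breeding costs next year's growth, population size is last year's size
times last year's vital rates. Then `X` is endogenous with respect to
`Y`, and static regressions (cross-sectional or within-subject-centred
mixed models) are biased on the short series that field studies actually
produce, in the direction opposite to the cross-lag's sign — towards
finding density dependence, and away from finding trade-offs or benefits
of group living. This package is for researchers who want to (i) see how
large that bias is for their study design, and (ii) fit dynamical models
that avoid it.

## What it provides

* **Simulator** (`process_spec()`, `simulate_panel()`) for four
  cross-lagged Gaussian processes — a life-history trade-off (single
  subject or many, with among-subject covariance `Omega` of correlated
  random intercepts), density dependence of a vital rate, and benefits of
  group living:

      Y[s,t] = a + b X[s,t] + mu[s] + eps[s,t]
      X[s,t] = c + d Y[s,t-1] (+ f Z[s,t-1] X[s,t-1]) (+ nu[s]) + kap[s,t]
      Z[s,t] = g (+ nu[s]) + lam[s,t]

  plus a measurement-error overlay (`add_measurement_error()`) that makes
  the error a stated fraction of total variance.
* **Estimators** (`crosslag_fit()` front end): static cross-sectional and
  within-subject-centred mixed models, a lagged-dependent-variable mixed
  model, a dynamical structural equation model (`fit_dyn_sem()`) that
  maximizes the exact marginal likelihood of the multi-equation system
  with correlated random intercepts integrated out analytically, and an
  errors-in-variables extension (`fit_dyn_sem_plus()`) with known
  measurement-error variances.
* **Monte-Carlo engine** (`run_grid()`, `run_sweep()`,
  `power_analysis()`) computing bias and power surfaces over subject
  counts, series lengths and parameter sweeps, with a paired-replicate
  design and full seed reproducibility — usable directly as a power tool
  for "more subjects vs. more years" design decisions.
* **Diagnostics**: the within-subject cross-lag correlation
  (`crosslag_correlation()`, necessary-not-sufficient evidence for a
  cross-lag) and the growth-and-plateau of `Var(X_t)`
  (`variance_growth()`) that governs how fast static bias fades.
* **Case-study pipeline** for count data: Bayesian Poisson/binomial
  models of cooperative-breeding group panels (`fit_wren_stat_within()`,
  `fit_wren_dyn_sem()` via JAGS) reporting the percent effect of one
  additional group member, plus a clearly synthetic group-dynamics
  generator (`simulate_wren_like()`) for testing them.

## Worked example

Simulate 100 subjects over 10 steps from the trade-off process
(`b = 0.5`, cross-lag `d = -0.5`, positive among-subject covariance) and
compare the standard within-subject mixed model with the dynamical SEM:

```r
library(crosslag)
spec <- process_spec("tradeoff_multi", n_subjects = 100, n_time = 10,
                     seed = 2024)
panel <- simulate_panel(spec)

fit_stat_within(panel)
#> STAT_WITHIN fit (100 subject(s), 1000 observations)
#>   b = 0.5309  (SE 0.0275, 95% CI [0.4769, 0.5848], p = 5.29e-83)
#>   standardized b (SD ratio): 0.4849;  log-likelihood: -1475.920

fit_dyn_sem(panel)
#> DYN_SEM fit [tradeoff] (100 subject(s), 1000 observations)
#>   b = 0.5037  (SE 0.0277, 95% CI [0.4494, 0.5580], p = 8.39e-74)
#>   standardized b (SD ratio): 0.4601;  log-likelihood: -2974.522
```

The within-subject static estimate overshoots the true `b = 0.5` (the
negative cross-lag biases it upward; over many replicates the bias is
about +6% at this design), while the dynamical SEM — which models the
cross-lag equation jointly with correlated subject intercepts — is
centred on the truth. The diagnostic confirms the cross-lag signature the
static model ignores:

```r
crosslag_correlation(panel)
#> Within-subject cross-lag correlation cor(X_t, Y_[t-1]) = -0.522
#>   900 pairs; 95% CI [-0.568, -0.473]; p = 2.2e-67
#>   Note: a cross-lag correlation is a necessary, not a sufficient,
#>   condition for a causal cross-lag.
```

Bias and power surfaces over a design grid:

```r
ex <- run_grid(process_spec("tradeoff_multi", seed = 1),
               subjects = c(10, 100), lengths = c(5, 10, 20),
               models = c("stat_within", "dyn_sem"), n_reps = 200,
               seed = 42)
plot(ex)
```

A thin command-line layer (`inst/cli/crosslag.R`) exposes the same
functionality as subcommands (`simulate`, `fit`, `experiment`, `sweep`,
`power`, `diagnose`, `casestudy`) driven by YAML/JSON configs; every
output carries a sidecar with the seed and config hash.

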