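# sharkocc

Daily occurrence of acoustically tagged sharks from passive telemetry.

Fixed acoustic receivers log a timestamped detection whenever a tagged
shark swims within range. `sharkocc` is for movement ecologists who want to
go from those raw detection logs to a defensible statement about *when*
individuals use a site and *why* that varies: it builds the daily
presence/absence series, summarises residency, and fits a hierarchical
Bayesian logistic occurrence model with seasonal and environmental
covariates, sex/length effects and individual-level random slopes —
including an exact treatment of an individual whose sex was never recorded.

## The model

A shark is scored **present** on a day if at least two of its detections
that day (on any receiver) fall strictly within 15 minutes of each other.
Residency is summarised by the **degree of occurrence**, DO = days
detected / inclusive span of detection days. Daily presence is then
modelled as

```
Y[i,t] ~ Bernoulli(p[i,t])
logit(p[i,t]) = beta0[i] + sum_j beta[j,i] * x*[j,t]      j = 1..4
beta0[i]      = alpha0 + alpha1 * male[i] + alpha2 * (length[i] - 220)
beta[j,i]     ~ Normal(mu[j], sigma[j])
```

with covariates `x1 = cos(2*pi*t/365)`, `x2 = sin(2*pi*t/365)`,
`x3 = log(chlorophyll)`, `x4 = temperature (°C)`, centred at the baseline
`(0, 0, 0, 28)`. For a shark of unrecorded sex, a parameter `pi` is the
probability it is male and its whole detection history is marginalized over
the two sex branches. Inference is MCMC (JAGS backend) with
rank-normalized split-Rhat and bulk/tail effective-sample-size diagnostics;
model checking uses Gelman–Hill binned residuals with a 95% posterior
predictive envelope; prediction covers individual, sex-specific,
population-marginal and sex-contrast occurrence curves.

## Worked example

Everything below runs from a synthetic cohort, so it works on a laptop
with no field data. `simulate_cohort()` draws individuals, environment and
daily presence from the generative model; `explode_to_detections()` turns
presence into a raw detection stream.

```r
library(sharkocc)

cfg <- sim_config(n_individuals = 8, study_start = as.Date("2016-01-01"),
                  study_end = as.Date("2017-12-31"))
sim <- simulate_cohort(cfg, seed = 1)
detections <- explode_to_detections(sim$presence, cfg, seed = 2)

presence <- detections |>
  filter_false_positives() |>      # >=2 same-tag hits within 30 min
  daily_presence()                 # strict 15-min two-detection rule

cohort_summary(degree_of_occurrence(presence))[c("n_retained", "do_mean", "do_sd")]
#> $n_retained
#> [1] 8
#> $do_mean
#> [1] 0.3969141
#> $do_sd
#> [1] 0.1930965
```

The cohort was detected on about 40% of monitored days. Now assemble the
centred design and fit:

```r
covars <- build_covariates(sim$environment)
tab <- assemble_model_table(presence, covars, sim$individuals)
fit <- fit_occurrence(tab, seed = 3)   # 4 chains x 2000, 1000 warmup
tidy(fit)
#> # A tibble: 12 × 7
#>    term              estimate std.error conf.low conf.high  rhat ess_bulk
#>  1 alpha0            -0.627     0.331    -1.32    0.00703   1.04     305.
#>  2 alpha1_male       -1.44      0.388    -2.27   -0.727     1.00    1158.
#>  3 alpha2_length     -0.0111    0.00572  -0.0233 -0.000805  1.01    1548.
#>  4 mu_cos             0.381     0.233    -0.0312  0.872     1.04     186.
#>  5 mu_sin             1.90      0.417     1.11    2.77      1.02     462.
#>  6 mu_logchl          0.0266    0.198    -0.391   0.403     1.02     258.
#>  7 mu_temperature    -0.00651   0.109    -0.221   0.218     1.03     229.
#>  8 sigma_cos          0.235     0.165     0.0134  0.619     1.04     185.
#>  9 sigma_sin          0.768     0.283     0.330   1.44      1.00     768.
#> 10 sigma_logchl       0.176     0.142     0.0130  0.529     1.03     157.
#> 11 sigma_temperature  0.128     0.0683    0.0288  0.297     1.01     421.
#> 12 pi                 0.342     0.241     0.0117  0.842     1.00     859.
```

Males are markedly less resident than females (`alpha1_male` credibly
negative), larger sharks slightly less resident, and the positive `mu_sin`
drives spring presence and autumn absence — the generating pattern. The
`rhat` column flags any parameter above 1.01; rerun with
`occ_sampler(preset = "long")` for a longer budget. Binned-residual
calibration and the population-marginal curve:

```r
env <- residual_envelope(fit, n_bins = 50, n_rep = 200, seed = 5)
mean(env$inside)
#> [1] 0.96
curve <- marginal_population_curve(fit, covars, seed = 4)
head(tibble::as_tibble(curve), 3)
#> # A tibble: 3 × 4
#>   date       p_mean p_lower p_upper
#> 1 2016-01-01  0.445   0.299   0.619
#> 2 2016-01-02  0.447   0.305   0.621
#> 3 2016-01-03  0.456   0.300   0.644
autoplot(curve)            # ribbon curve; autoplot(env) for the residuals
```

`run_pipeline(run_config(...))` chains all of the above (read or simulate
inputs → screen → presence → design → fit → diagnostics → curves) and
writes CSV artifacts plus a JSON summary.

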