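# epimoderate

Epigenetic pacemaker models and the detection of epigenetic aging
moderators, in R.

Epigenetic clocks — penalized regressions that predict chronological age
from DNA-methylation beta values — are the workhorse of age-acceleration
studies, but precisely because they minimize the age-prediction error they
tend to suppress the influence of the factors those studies are after: sex,
cell-type composition, toxin exposure, health status. The epigenetic
pacemaker (EPM) inverts the modeling direction. Each CpG site $i$ is linear
in a latent per-sample **epigenetic state** $s_j$,

$$\hat m_{ij} = m^0_i + r_i s_j + \epsilon_{ij},$$

and all of $m^0_i$ (baseline methylation), $r_i$ (rate of change) and $s_j$
are estimated by a fast conditional expectation-maximization that minimizes
the total squared methylation error: per-site OLS fits with states held
fixed, then a closed-form per-sample state update
$s_j = \sum_i r_i(\hat m_{ij} - m^0_i)/\sum_i r_i^2$, iterated from an
age-based initialization until the error reduction stalls. The state is
year-like but free to be non-linear in age, and it retains the imprint of
factors that moderate epigenetic aging.

The package provides:

* **`fit_epm()` / `predict_states()`** — the pacemaker, with broom-style
  `tidy()`/`glance()`, `autoplot()`, and a state-to-years helper
  (`fit_state_age_map()`);
* **a simulation framework** (`trait_spec()`, `simulate_cohort()`,
  `simulate_methylation()`, `benchmark_design()`,
  `simulate_celltype_fractions()`) that generates beta-value matrices from
  planted age-associated phenotypes $p_{k,j} = \mathrm{Age}_j^{\gamma_k}
  q_{k,j}$, including a sex-like binary exposure and a latent health factor;
* **an elastic-net clock comparator** (`fit_clock()`, `predict_age()`,
  `fit_metrics()`) via glmnet, with both cross-validated and fixed
  (scikit-learn-convention) penalties;
* **a site-selection pipeline** (`pcc_filter()`, `mae_screen()`,
  `cluster_residuals()` with a built-in affinity-propagation
  implementation, `evaluate_clusters()`, `merge_clusters()`);
* **moderation analysis** (`build_design()`, `fit_moderation()`,
  `fit_celltype_pca()`, `significance_summary()`) — OLS of the epigenetic
  state or clock age on age, √age and candidate moderators;
* **experiment drivers** (`run_simulation_grid()`,
  `run_build_and_moderate()`) plus TSV/YAML I/O and a thin CLI at
  `inst/scripts/epm-tools.R`.

## Worked example

Simulate the benchmark design — 61 traits (including one sex-like binary
exposure with on-exposure 0.995 and a health factor with sd 0.005) observed
at 400 sites for 500 samples — fit both models on a random half, and test
for moderators on the held-out half:

```r
library(epimoderate)

design <- benchmark_design(binary_q = 0.995, health_sd = 0.005, seed = 1)
cohort <- simulate_cohort(500, c(0, 100), health_sd = 0.005,
                          traits = design$traits, seed = 2)
betas  <- simulate_methylation(cohort, design$sites, seed = 3)
halves <- split_half(betas, cohort, seed = 4)

epm <- fit_epm(halves$train$matrix, halves$train$cohort$age)
epm
#> Epigenetic pacemaker fit
#>   sites: 400  samples: 250
#>   iterations: 3 (converged)
#>   final SSE: 11.3725

states <- predict_states(epm, halves$test$matrix)
clock  <- fit_clock(halves$train$matrix, halves$train$cohort$age,
                    penalty = 1, seed = 5)
ages_hat <- predict_age(clock, halves$test$matrix)
fit_metrics(halves$test$cohort$age, ages_hat)
#> # A tibble: 1 × 2
#>   r_squared   mae
#>       <dbl> <dbl>
#> 1     0.893  8.11

d <- build_design(halves$test$cohort$age,
                  covariates = list(health = halves$test$cohort$health,
                                    binary = halves$test$cohort$on_bin1))
tidy(fit_moderation(states, d, "epm_state"))
#> # A tibble: 5 × 6
#>   outcome   term        estimate std.error statistic   p.value
#>   <chr>     <chr>          <dbl>     <dbl>     <dbl>     <dbl>
#> 1 epm_state (Intercept) -14.2      0.0505    -281.   1.50e-309
#> 2 epm_state age           0.582    0.00138    422.   0
#> 3 epm_state sqrt_age      5.26     0.0173     304.   6.83e-318
#> 4 epm_state health       19.5      1.53        12.7  6.85e- 29
#> 5 epm_state binary       -0.0533   0.0152      -3.51 5.29e-  4

tidy(fit_moderation(ages_hat, d, "clock_age"))
#> # A tibble: 5 × 6
#>   outcome   term        estimate std.error statistic   p.value
#>   <chr>     <chr>          <dbl>     <dbl>     <dbl>     <dbl>
#> 1 clock_age (Intercept)  10.3      0.0453     227.   1.20e-286
#> 2 clock_age age           0.511    0.00124    413.   0
#> 3 clock_age sqrt_age      2.11     0.0155     136.   9.42e-233
#> 4 clock_age health       13.2      1.37         9.61 9.52e- 19
#> 5 clock_age binary       -0.0161   0.0136      -1.18 2.39e-  1
```

The reading: both models track age almost perfectly (the age and √age
terms), but the 0.5% binary exposure — a sex-like decelerator planted in
the simulation — is significant for the pacemaker state
(p = 5.3 × 10⁻⁴) and invisible to the clock (p = 0.24), while the clock
remains the better pure age predictor. That asymmetry, aggregated over many
replicates and a grid of effect sizes (`run_simulation_grid()`), is the
package's central result: the epigenetic state is the more sensitive
instrument for discovering aging moderators.

For real-style matrices, `run_build_and_moderate()` chains the site screens
(|PCC| > 0.4, per-site MAE < 0.025), affinity-propagation clustering of
regression residuals, cross-validated cluster evaluation, merging of
clusters with MAE < 6 years, final model fits, and the moderation
regression with cell-type principal components and a sex term (dropped when
the batch is more than 70% female).

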