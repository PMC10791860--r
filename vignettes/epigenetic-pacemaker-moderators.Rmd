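---
title: "The epigenetic pacemaker and the detection of aging moderators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The epigenetic pacemaker and the detection of aging moderators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimoderate)
library(dplyr)
```

## The problem

Epigenetic clocks predict chronological age from DNA-methylation beta
values by penalized regression. Because they are trained to minimize the
age-prediction error, they tend to discard exactly the signal that makes
age-acceleration studies interesting: methylation sites whose trajectories
are shifted by sex, cell-type composition, toxin exposure or health status.
The epigenetic pacemaker (EPM) takes the opposite view — it models the
methylation data, not the age — and therefore retains the influence of such
moderators in its output.

`epimoderate` implements both models, a simulation framework that generates
methylation matrices with planted age-accelerating factors, a site-selection
pipeline for building EPM models on real-style data, and the moderation
regression used to test whether a factor shifts the epigenetic state or the
epigenetic age.

## The pacemaker model

Each site $i$ is modeled as linear in a latent per-sample epigenetic state
$s_j$:

$$\hat m_{ij} = m^0_i + r_i s_j + \epsilon_{ij},$$

with a site-specific baseline $m^0_i$ (beta units), rate of change $r_i$
(beta units per state unit) and a normal error. The state is shared by all
sites of a sample, and unlike chronological age it may be a non-linear
function of age. Fitting minimizes the total squared methylation error by a
conditional expectation-maximization (block coordinate descent):

1. initialize $s_j$ at the chronological ages;
2. fit each site's $(m^0_i, r_i)$ by ordinary least squares given the states;
3. update each state by its closed-form least-squares minimizer
   $s_j = \sum_i r_i(\hat m_{ij} - m^0_i) \,/\, \sum_i r_i^2$;
4. repeat until the relative reduction in the total squared error falls
   below `tol`.

The closed-form state update is the exact minimizer of the per-sample sum of
squares, so the error trace is non-increasing by construction — the test
suite asserts this on every fit. The model is identifiable only up to an
affine transform of the states; the age initialization anchors the scale, so
states come out "year-like". Two numerical consequences follow. First, on
noiseless linear data the age initialization is already the fixed point and
the algorithm stops after verifying it (two iterations). Second, rescaling
the initialization rescales the solution exactly (states $\times c$, rates
$\div c$), which we test as an affine-equivariance property.

Defaults: `tol = 1e-4` (relative error reduction) and `max_iter = 100`.
Convergence on the simulated benchmarks takes 3–6 iterations. Matrices must
be complete; imputation is upstream of this package.

Because states are not years, prediction error "in years" requires a
convention. We fit $s = a + b\,\mathrm{age} + c\sqrt{\mathrm{age}}$ on
training data and invert it numerically (monotone grid inversion on a dense
age grid). This mapping is used only for reporting year-denominated errors,
e.g. in cluster evaluation; moderation fits use raw states by default, with
a configuration switch for year-mapped states — the $\sqrt{\mathrm{age}}$
term of the moderation design absorbs the state's non-linearity either way.

## The simulation framework

The simulator works phenotype-first: define age-associated traits, realize
them per sample, then derive methylation consistent with them.

A trait $k$ contributes a phenotype
$p_{k,j} = \mathrm{Age}_j^{\gamma_k}\, q_{k,j}$: the exponent $\gamma_k$ is
a characteristic of the trait (drawn once per trait; $\gamma = 1$ linear,
$0 < \gamma < 1$ non-linear, $\gamma = 0$ age-independent) and the exposure
$q_{k,j}$ is a per-sample coefficient whose deviation from 1 accelerates or
decelerates that trait's contribution. Health-coupled traits draw their
exposure centered on $1 + h_j$, where $h_j \sim N(0, \mathrm{health\_sd}^2)$
is a latent per-sample health factor shared by all coupled traits. A binary
(sex-like) trait takes exposure `binary_q` with probability 0.5 and 1
otherwise.

A site responds to a non-negative weighted sum of its assigned traits:

$$\hat m_{ij} = \mathrm{clamp}\!\left(m^0_i + r_i \textstyle\sum_k w_{ik}
p_{k,j} + \epsilon_{ij},\; 0,\; m^{max}_i\right).$$

The benchmark design (`benchmark_design()`) contains 61 traits — 10
health-coupled and 20 age-only traits with $\gamma \sim N(0.5, 0.01^2)$, 10
and 20 more with $\gamma \sim N(1, 0.01^2)$, and one binary trait with
$\gamma = 0.5$ — and 400 sites: five per continuous trait, 50 for the
binary trait, and 50 mixture sites equally weighted (1/5) over four random
continuous traits plus the binary trait. A switch pads the design to a
different total (e.g. 450) with additional single-trait sites.

### Parameter choices

Site-level parameters are drawn as: baseline $m^0 \sim U(0.05, 0.35)$ for
hypermethylating sites and $U(0.65, 0.95)$ for hypomethylating ones
(direction chosen with probability 1/2); $|r_i|$ scaled so the expected beta
range across the cohort's age span is $U(0.1, 0.5)$; noise
$\sigma_i \sim U(0.003, 0.01)$; ceiling $m^{max} = 1$. These keep sites
age-informative (they pass a 0.4 correlation screen) while staying inside
$[0, 1]$ — fewer than 5% of entries clamp at default settings, and the
clamp count is recorded on the matrix.

The intrinsic exposure noise of continuous traits, `sample_effect_sd`,
defaults to 0: age-only traits are deterministic functions of age
(intrinsic epigenetic aging), and health-coupled traits' exposure is
exactly $1 + h_j$. All per-sample variation around the age trend therefore
flows through the two moderators (health and binary status) plus
measurement noise. We chose this after examining the alternatives
quantitatively: giving every continuous trait an exposure sd of 0.05 makes
the per-sample state noise so large that a health shift of order 0.002 or a
0.5% binary exposure is undetectable at $n = 500$ — both models' moderation
tests then sit two orders of magnitude away from the regimes the moderation
analysis is designed to probe. With the deterministic default, both the
pacemaker and the clock operate in the intended signal-to-noise regime, and
the parameter remains available for users who want extra exposure noise.

All randomness flows from one integer seed through deterministic
sub-streams (`substream_seed()`): each trait, site, replicate and fold draws
from its own stream, so adding sites to a design does not perturb earlier
draws and every grid cell is reproducible in isolation. Fixed seeds give
bit-identical matrices and byte-identical result files.

### What the simulator does and does not emulate

It emulates the statistical structure that matters for moderator detection:
beta values in $[0, 1]$, age-correlated trajectories with heterogeneous
non-linear forms, shared latent factors, compositional cell-type covariates
(Dirichlet draws with an optional age drift in concentration). It does not
emulate probe chemistry, batch effects, detection failures, missing values
or longitudinal sampling. Tests passing on simulated data therefore show
that the algorithms are correct and that the moderation contrast behaves as
designed — not that effect sizes on a particular array dataset will match.

## The benchmark experiment

`run_simulation_grid()` crosses the binary on-exposure (0.995 to 1.0, five
values) with the health sd (0.0 to 0.01, five values). Each replicate
simulates 500 samples, splits them in half, fits the pacemaker and the
elastic-net clock on the training half, predicts states and ages for the
held-out half, and fits

$$S_j = \beta_0 + \beta_1\,\mathrm{Age} + \beta_2 \sqrt{\mathrm{Age}} +
\beta_3\, \mathrm{health}_j + \beta_4\, \mathrm{binary}_j + e_j$$

for both outcomes, collecting the term p-values. At the health-sd = 0 cells
the health covariate is identically zero and is dropped from the design
(recorded on the design object); genuine collinearity among non-constant
terms is an error instead. The test suite runs this experiment at full
scale — 50 replicates of 500 samples for the binary contrast, 50 for the
low-sd health contrast, 200 null replicates — and `scripts/acceptance.R`
recomputes the same quantities from scratch.

## The clock comparator

The clock is elastic-net regression of age on beta values,

$$L(\lambda_1, \lambda_2, \beta) = |y - X\beta|^2 + \lambda_2|\beta|^2 +
\lambda_1|\beta|,$$

delegated to glmnet; this package owns only the data contract,
hyper-parameters (`l1_ratio = 0.75`, `cv = 5`), seeding and metrics. Two
penalty modes exist: a cross-validated path (used by the site-selection
pipeline) and a fixed total penalty of 1 in the scikit-learn-style
parameterization (used by the simulation grid). One numerical subtlety is
worth recording: glmnet standardizes the response internally, which rescales
the L1 and L2 penalty components differently, so no single glmnet `lambda`
reproduces the fixed-penalty objective with unstandardized predictors. The
fixed-penalty branch therefore pre-standardizes the response by its
population sd and solves with a transformed `(lambda, alpha)` pair, which
recovers the stated objective exactly; a test checks the solution against an
independent coordinate-descent minimizer.

## The site-selection pipeline

For real-style matrices (`run_build_and_moderate()`), models are built on a
screened site set:

1. **Correlation screen** — keep sites with $|\mathrm{PCC}|$ between
   methylation and age above 0.4 (0.45 for smaller, noisier cohorts);
   zero-variance sites are excluded and logged.
2. **Error screen** — per-site OLS of methylation on age; keep sites with
   MAE below 0.025 beta units; keep the residual vectors.
3. **Residual clustering** — affinity propagation on the negative squared
   Euclidean distances between residual vectors (preference −2.5, damping
   0.9, at most 1000 iterations), grouping sites with a shared functional
   form. Affinity propagation is implemented in the package (no suitable
   implementation ships with the environment's R libraries) and is checked
   against a reference implementation's output on a fixture; a tiny seeded
   jitter breaks ties deterministically, and non-convergence degrades to
   singleton labels with a warning rather than an error.
4. **Cluster evaluation** — for clusters with more than 10 sites, 5-fold
   cross-validated pacemaker and elastic-net models; pacemaker errors are
   year-mapped via the square-root trend fit on the training folds. Five
   folds match the clock's cross-validation; the trend $R^2$ of cluster
   states against the age trend is reported (a common display filter at
   $R^2 \ge 0.4$) but is not a merge criterion.
5. **Merge** — union the sites of clusters whose pacemaker *and* clock CV
   MAEs are both below 6 years; final models are fit on the merged set, and
   a full variance-filtered ($\ge 0.001$) clock is fit as a second
   comparator.

Held-out states and ages then enter the moderation regression with
covariates appropriate for real data: the first three principal components
of cell-type abundance fractions (PCA fit on training samples only and
applied to test samples) and a 0/1 sex term, dropped when more than 70% of
samples are female. A reference-anchored quantile normalization by probe
type is available as optional preprocessing; on simulated data it is a
no-op by default because simulated sites have no probe-type structure.

## Design choices and open corners

* **State update formula.** The literature states the objective (minimize
  methylation error in $s_j$) without the formula; the closed form above is
  its exact minimizer and is verified against brute-force 1-D minimization.
* **Site-count default.** The enumerated benchmark design yields 400 sites;
  the design function exposes the total as configuration (`n_total_sites`),
  padding with additional single-trait sites, because descriptions of this
  class of experiment sometimes quote a larger matrix than the enumerated
  parts; padding does not change the qualitative contrasts.
* **Raw vs year-mapped states in moderation.** Default raw; the square-root
  age term absorbs the non-linearity, and the year mapping is available as
  a switch (`year_mapped_states`).
* **Bonferroni divisor.** `significance_summary()` exposes the threshold as
  `alpha / n` with `n` configurable; `0.05 / 13 ≈ 0.00385` reproduces the
  commonly used 0.0038-style cutoff.
* **Classical standard errors.** The moderation OLS uses classical (not
  robust) standard errors; the simulated errors are homoscedastic and the
  null calibration test confirms uniform p-values.

## Problem sizes used in the checks

The shipped test suite and acceptance script run the binary contrast with
50 replicates of 500 samples (pooled over the health grid), the low-sd
health contrast with 50 replicates, the null calibration with 100–200
replicates, and the end-to-end pipeline check with 10–20 replicates of 500
samples; the conditional-EM exactness checks use small noiseless fixtures
where the answer is known in closed form. These sizes give Monte-Carlo
standard errors on reported mean p-values of roughly 0.01–0.02, small
enough to place each result in the correct significance regime.

## Known limitations

* The latent state is a single scalar per sample; multi-dimensional aging
  programs are out of scope.
* Missing beta values are not handled; impute upstream.
* The simulator's site-parameter distributions are package conventions —
  plausible for blood 450K-style data but not estimated from any dataset —
  so absolute simulated effect sizes should be read comparatively (pacemaker
  vs clock under identical conditions), not as calibrated predictions for a
  particular cohort.
* Affinity propagation is quadratic in the number of screened sites; for
  matrices with tens of thousands of surviving sites, tighten the screens
  first.

## A minimal session

```{r example, eval = FALSE}
design <- benchmark_design(binary_q = 0.995, health_sd = 0.005, seed = 1)
cohort <- simulate_cohort(500, c(0, 100), health_sd = 0.005,
                          traits = design$traits, seed = 2)
betas <- simulate_methylation(cohort, design$sites, seed = 3)
halves <- split_half(betas, cohort, seed = 4)

epm <- fit_epm(halves$train$matrix, halves$train$cohort$age)
glance(epm)
states <- predict_states(epm, halves$test$matrix)

clock <- fit_clock(halves$train$matrix, halves$train$cohort$age,
                   penalty = 1, seed = 5)
ages_hat <- predict_age(clock, halves$test$matrix)

design_mat <- build_design(
  halves$test$cohort$age,
  covariates = list(health = halves$test$cohort$health,
                    binary = halves$test$cohort$on_bin1)
)
tidy(fit_moderation(states, design_mat, "epm_state"))
tidy(fit_moderation(ages_hat, design_mat, "clock_age"))
```
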