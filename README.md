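# thyrolife

A discrete-time Markov chain model of **functional thyroid disease over
the lifetime**, for epidemiologists and modellers who need realistic
individual life-courses of thyroid status — e.g. to predict incidence
rates of treated disease from prevalence data, or to drive
microsimulations in which thyroid state affects other physiology.

Each person occupies one of seven states at every quarterly step of ages
[0, 80): normal (1), overt hypothyroid (2), overt hyperthyroid (3),
subclinical hypothyroid (4), subclinical hyperthyroid (5), treated-ever
(6, absorbing) and reverted-to-normal (7, absorbing). Transitions `tij`
cover onset (sex- and decade-specific `t14`, `t15`), progression
(`t42`, `t53`), reversion (`t47`, `t57`) and treatment (`t46`, `t56`,
`t26`, `t36`); each row of the transition matrix sums to one.

The package implements the full calibration pipeline around that chain:

1. **Meta-analytic priors** — published cohort counts (N, years, cases)
   are inverted to annual probabilities via
   `Pfu = 1 − (1 − pa)^n`, `var(pa) = pa(1−pa)/N`, pooled with
   fixed-effect inverse-variance weights, and — together with a 3× rule
   on published treated-disease incidence for the onset rows — expressed
   as maximum-variance beta/Dirichlet priors (smallest concentration
   pinned at 1.05) on the quarterly scale.
2. **Target tables** — survey-like records are classified by TSH/fT4
   thresholds with the survey's exclusion rules, and diagnosed counts
   are adjusted by a 95% functional fraction.
3. **Bayesian calibration** — binomial (diagnosed) + multinomial
   (undiagnosed) likelihood over sex × decade cells against analytic
   prevalences obtained by matrix propagation; adaptive
   Metropolis-within-Gibbs posterior sampling; MAP extraction and
   diagnostics.
4. **Microsimulation & evaluation** — simulated cohorts (80,000/sex by
   default), treated hypo-/hyperthyroidism incidence with exact Poisson
   CIs, fold-ratio comparison against published incidence, CV-based
   identifiability screening and sensitivity scenarios.
5. **Synthetic data** — a seeded generator of survey-like unit records
   from any known parameter set, used for the parameter-recovery tests.

See the methods vignette (`vignettes/thyrolife-methods.Rmd`) for the
model's assumptions, parameter meanings, numerical conventions and
limitations.

## Worked example

```r
library(thyrolife)

# Pooled annual transition probabilities from the bundled study table
pooled_transitions()
#>   transition n_studies pooled_pa
#> 1        t26         2    0.2051
#> 2        t36         2    0.1689
#> 3        t42         7    0.0218
#> 4        t47         5    0.0765
#> 5        t53         2    0.0344
#> 6        t57         2    0.0627

# Priors, prior-mean parameter set, analytic prevalence
pri <- build_priors()
mp  <- prior_mean_params(pri)
pp  <- predicted_prevalence(mp)
subset(transform(pp, pct = round(100 * proportion, 2)),
       sex == "female" & category == "treated", c(age_group, pct))
#>    age_group   pct
#>       20-29   0.56
#>       30-39   2.37
#>       40-49   5.65
#>       50-59  10.24
#>       60-69  15.37
#>       70-79  20.26

# Fold-ratio evaluation of the bundled reference calibration against the
# published incidence benchmark
fold_comparison(flynn_incidence(), reference_predicted_incidence())
#> 23 of 28 cells (82%) within a 4-fold window
```

The pooled `t42` of 0.0218/year prints as the published 0.02; the
prevalence column shows lifetime treated-disease prevalence rising with
age under the prior means (the calibrated values are obtained with
`sample_posterior()`); the last line reproduces the published evaluation
that 82% of predicted incidence cells fall within 4-fold of the
published rates.

An end-to-end run (priors → synthetic survey → targets → calibration →
simulation → evaluation) with seeded, hashed artifacts:

```r
run_pipeline(list(out_dir = "run1", seed = 1,
                  mcmc = list(n_chains = 3, n_iter = 5000, n_warmup = 2500)))
```

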