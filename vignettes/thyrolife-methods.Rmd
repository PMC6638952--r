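---
title: "A life-course Markov chain model of functional thyroid disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A life-course Markov chain model of functional thyroid disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrolife)
```

## The model

`thyrolife` implements a discrete-time Markov chain describing the
functional thyroid status of one person over ages [0, 80). At every
quarterly step each person occupies one of seven states:

| code | state | biochemistry |
|------|-------|--------------|
| 1 | normal | TSH and fT4 in range |
| 2 | overt hypothyroid | TSH high, fT4 low |
| 3 | overt hyperthyroid | TSH low, fT4 high |
| 4 | subclinical hypothyroid | TSH high, fT4 in range |
| 5 | subclinical hyperthyroid | TSH low, fT4 in range |
| 6 | treated (ever) | diagnosed/treated; absorbing |
| 7 | reverted to normal | biochemically normal; absorbing |

Allowed transitions follow the natural history of disease: onset
(1→4, 1→5), progression (4→2, 5→3), treatment (4→6, 5→6, 2→6, 3→6) and
reversion (4→7, 5→7). The transition probability `tij` denotes a move
from state `i` to `j` per step; the diagonal is the complement of each
row, so every transition matrix is exactly row-stochastic. Onset
probabilities `t14` and `t15` are sex- and decade-of-age-specific
(2 sexes × 7 decades, ages 10–79); the remaining eight probabilities are
scalars. Below age 10 the incidence of thyroid disease is negligible and
everyone is held in the normal state. That gives 36 free probabilities
in total (the two onset surfaces contribute 28, the scalars 8; published
accounts of this model class quote "32 parameters" for the same
enumeration — we count the rows actually present).

Key modelling assumptions, inherited from the model class this package
implements:

* first-order Markov dynamics — no dependence on disease history, hence
  no hyper→hypo swings (no 3→2 path) and no re-entry from the reverted
  state (no 7→4/7→5);
* no mortality, migration or calendar-time effects;
* states 6 and 7 are absorbing; "treated" aggregates hypo- and
  hyperthyroid treatment.

### Time step

Published natural-history data give *annual* risks, while thyroid status
can change within months, so the chain steps quarterly. Annual
probabilities are converted arrow-by-arrow with the compounding rule
`pq = 1 − (1 − pa)^{1/4}` (`annual_to_quarterly()`), and the diagonal is
rebuilt as the row complement. Converting each outgoing arrow
independently slightly mis-states competing risks, but at the magnitudes
involved (annual risks mostly below 0.2) the distortion is second order;
if a converted row ever exceeded probability one the package raises an
error rather than renormalising silently. Should a different convention
be preferred, only the two conversion helpers would change.

## A-priori transition probabilities

For progression, reversion and treatment of overt disease, published
cohorts report (N subjects, years of follow-up, cases). Each row is
turned into an annual probability by inverting the follow-up proportion:
with `n` the follow-up rounded to the nearest whole year and
`Pfu = cases / N` (or the published proportion where the two differ),
`pa` solves `Pfu = 1 − (1 − pa)^n`, with `var(pa) = pa(1 − pa)/N`
(`pa_from_followup()`). Rows for the same transition are pooled by
fixed-effect inverse-variance weighting (`pool_estimates()`); the
package cross-checks this against `metafor`'s fixed-effect estimator in
the test suite. The bundled study table (`natural_history_records()`)
carries two bookkeeping flags: one reversion estimate is excluded from
its pool as an outlier contaminated by iatrogenic cases, and the two
rows derived from an 11.1-year secondary source are marked
non-reproducible because their published `pa` cannot be recovered from
the printed counts under the stated formula (the package reports the
recomputed values; with them the pooled treatment probability for overt
hypothyroidism still reproduces the published 0.21, while the overt
hyperthyroidism pool comes out at ~0.17 against a published 0.16).

No usable cohorts exist for onset (`t14`, `t15`) or for treatment of
subclinical disease (`t46`, `t56`). Onset prior means are three times
the sex/decade-specific incidence rates of *treated* disease from the
Tayside record-linkage study (`flynn_onset_priors()`; prior mean in % =
3 × rate per 1000 person-years / 10), and `t46`/`t56` are assigned
0.02/year (configurable).

### Prior distributions

Rows with several exits (states 1, 4, 5) get Dirichlet priors over
(exits, stay); single-exit rows (2, 3) get beta priors. Concentrations
are chosen so the prior mean equals the target mean exactly while the
smallest concentration parameter is pinned at 1.05
(`make_prior()`): pushing the smallest parameter towards 1 maximises the
variance, and holding it just above 1 keeps the density mode strictly
inside (0, 1). Whether priors live on the annual or quarterly scale is
not fixed by the published account; since the chain steps quarterly,
`build_priors()` converts the pooled annual means to the quarterly scale
first and parameterises the distributions there, reporting both scales
in its CSV output. (This is also the likely source of the small
differences between published "mean a priori" columns and the raw
pooled values — e.g. 1.88% vs 2.2% for `t42`; the package surfaces both
numbers rather than forcing agreement.)

## Target tables

Calibration data are sex × decade (20–79) prevalence tables built from
survey-like unit records (`build_target_tables()`):

* **Diagnosed table** — everyone aged 20–79 without a thyroid-cancer
  history; a case is a reported thyroid diagnosis or use of thyroid
  medication. Because roughly 5% of reported disease is nonfunctional
  (goitre, nodules), diagnosed counts are multiplied by a functional
  fraction (default 0.95, half-up rounding per cell) before entering the
  likelihood.
* **Undiagnosed table** — additionally excludes diagnosed subjects,
  pregnancy/breastfeeding, self-reported poor health,
  chemotherapy/dialysis, hormone-interfering drugs and missing hormones;
  the rest are classified from serum TSH (µIU/mL) and fT4 (ng/dL):
  overt hypo TSH > 4 & fT4 < 0.5; subclinical hypo TSH > 4 with fT4 in
  [0.5, 1.28]; overt hyper TSH < 0.2 & fT4 > 1.28; subclinical hyper
  TSH < 0.2 with normal fT4; TSH in [0.2, 4] is normal. Boundary values
  are normal-range (the inequalities are strict). Patterns violating
  concordance (TSH > 4 with fT4 > 1.28, or TSH < 0.2 with fT4 < 0.5)
  fit no modelled state; they are dropped from the undiagnosed table
  and counted in an attribute, a choice this package makes explicitly
  since the source account does not address them.

Survey weights are not implemented; synthetic records are
self-weighting, and ingestion of real survey files is out of scope.

## Likelihood and calibration

The analytic prevalence engine (`propagate()`) advances the occupancy
vector from all-normal at birth through 320 quarterly matrix products;
`predicted_prevalence()` averages the 40 quarterly occupancy vectors in
each decade (averaging over quarters rather than integer ages is an
arbitrary but fixed convention; the difference is negligible). Observed
"normal" maps to states 1 + 7 — state 7 is biochemically normal, and no
other mapping is consistent with the observable categories. Undiagnosed
category probabilities are conditioned on not being treated, mirroring
the survey design in which hormone classification applies only to those
without a diagnosis.

Each diagnosed cell contributes a binomial log-probability of the
functional-adjusted count given the predicted state-6 prevalence; each
undiagnosed cell contributes a multinomial log-probability over the five
categories (`log_likelihood()`). Cells with zero denominator contribute
nothing; an impossible observation yields −∞. The 10–19 decade has no
prevalence data and is informed only through its effect on the 20–29
occupancy. For speed, the propagation is evaluated through an
algebraically equivalent sparse recursion (cumulated products/filters;
verified against the dense matrix route to 1e−12 in the tests).

`sample_posterior()` draws from the posterior with an adaptive
Metropolis-within-Gibbs sampler. Each Dirichlet row is one proposal
block on the additive-log-ratio scale (reference category "stay"); the
two beta scalars use log-odds. Block proposal scales adapt every 50
warm-up iterations towards acceptance rates of 0.3 (0.44 for scalars)
and are frozen afterwards, so the post-warm-up chain is a valid Markov
chain. Chains start from independent prior draws, which guarantees
valid initial states. Defaults follow the published design (3 chains ×
5000 iterations, 2500 warm-up, 7500 retained draws); the test suite
runs reduced versions. Convergence is summarised by split-chain R-hat
(flagging, not discarding, runs with any R-hat > 1.05) and an
autocorrelation-based effective sample size. The original analysis used
a Hamiltonian Monte Carlo engine; any correct sampler over these
constrained parameters is acceptable, and correctness here is
established by prior-recovery (flat-likelihood runs reproduce prior
means within Monte-Carlo error) and parameter-recovery experiments, not
by matching any particular chain. The reported MAP follows the
published convention: the sampled draw maximising the *likelihood*
(the prior×likelihood maximiser is also stored).

## Simulation and evaluation

`simulate_population()` steps individuals through the same matrices
(default 80,000 per sex, matching the published simulated population),
recording occupancy counts, first entries into the treated state with
their source state, and person-years at risk. Treated-hypothyroidism
events enter from states 4 or 2, hyperthyroidism from 5 or 3 — source
attribution is the only way to split the single treated state into the
two published outcome rates. Person-time stops at first treatment;
reverted individuals stay in the denominator (they cannot re-enter
disease states in this model, but a population denominator would include
them). Incidence rates per 1000 person-years carry exact Poisson
(Garwood) 95% intervals — the published account does not state its
interval method, so the exact interval is used.

`fold_comparison()` compares predicted and published incidence cell by
cell; a cell is "within k-fold" when the ratio lies in [1/k, k]
*inclusive* — the inclusive bound is what reproduces the published 82%
figure, since one of the 28 cells sits at a ratio of 3.99.
`cv_screen()` retains draws within 4 BIC units of the best draw (with
parameter count and sample size constant, ΔBIC reduces to twice the
log-likelihood deficit) and ranks parameters by the coefficient of
variation over that subset. `run_sensitivity()` re-runs the calibration
under the published sensitivity scenarios: flat priors, minimum
concentration 1.5 (variance reduced, means preserved), `t42`/`t47`
priors pooled from the two referral cohorts only (annual means ≈ 0.05
and 0.06), and a functional fraction of 0.85.

## Synthetic data

The per-cell unit-record counts behind the published target tables are
not public, so `synthetic_design()`/`generate_records()` create
survey-like records with the same structure from a known parameter set:
a diagnosed-table total of 16,453 split uniformly over the 12
sex × decade cells, a one-third hormone subsample, a 5% nonfunctional
share of diagnoses sprinkled over biochemically normal subjects, and
per-category rectangular (TSH, fT4) sampling regions nested strictly
inside the classification thresholds, so with the default noise-free
regions classification recovers the latent state exactly.
`generate_counts()` draws the same tables directly from the binomial /
multinomial sampling law with the analytic cell probabilities; the test
suite checks the two routes agree in distribution over 20 seeds.

What the generator does *not* emulate: realistic continuous TSH/fT4
population distributions (values are uniform in boxes), survey
weighting, item nonresponse patterns, or misclassification near the
thresholds. Passing recovery tests therefore demonstrate that the
estimation machinery is self-consistent at survey scale — not that the
model fits any particular real population.

## Numerical choices and problem sizes

* Row-stochasticity is enforced exactly by construction and asserted to
  1e−12; occupancy conservation to 1e−10.
* The sparse propagation recursion is the likelihood hot path
  (~2 ms per sex per evaluation); it is checked against the dense
  matrix product for random parameter sets.
* Monte-Carlo agreement between simulation and the analytic engine is
  tested per (quarter-age, state) cell with 3-binomial-SE bands plus a
  1/n discreteness allowance. A band test over ~2,200 correlated cells
  per cohort cannot demand that *every* cell be in band — 0.3% of cells
  fall outside 3 SEs even under exact agreement — so the criterion is
  that at least 99% of cells are in band (expected rate 99.7%), applied
  at n = 200,000 per sex for five prior-drawn parameter sets.
* The parameter-recovery experiment generates targets at survey scale
  (16,453) from the prior-mean parameter set — the natural recovery
  design, mirroring the published internal-consistency claim that MAP
  values stay within 3-fold of their priors for 29 of the parameters —
  and runs a reduced sampler (3 × 1500, 750 warm-up) so the whole test
  suite completes in minutes. Weakly-informed parameters (notably the
  hyperthyroid branch and the 10–19 onsets) are held near truth mostly
  by their priors; strongly-informed ones by the data.
* Degenerate inputs: `Pfu = 1` errors (no finite annual risk);
  `Pfu = 0` yields a flagged degenerate zero-variance estimate; empty
  target cells are recorded with zero denominators and skipped; a
  treated prevalence of 1 makes conditional categories undefined and is
  guarded.

## Known limitations

* The exact published likelihood and annual→quarterly conversion live in
  an unavailable supplement; both are reimplemented from the main-text
  description and flagged above where a convention had to be chosen.
* Without the true per-cell survey denominators, the published posterior
  (fitted prevalence tables, predicted incidence CIs) is not
  reproducible bit-for-bit; the package's calibration claims rest on the
  recovery properties plus the desk-scale published quantities it does
  reproduce.
* No death state and no history dependence; the incidence of treated
  disease is attributed to hypo/hyper by the immediately preceding
  state only.
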