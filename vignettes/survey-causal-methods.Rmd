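---
title: "Survey-weighted matching and weighting methods: models, design choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey-weighted matching and weighting methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`svycausal` studies how complex-survey weights and design should enter
matching- and weighting-based causal inference. This vignette is the
package's own account of the models it simulates, the estimators it
implements, the numerical choices made where the design was genuinely
open, and what the simulation does and does not establish about real data.

## The simulated population

The target population is a stratified area frame: `n_bg = 752` census
block groups (BGs) split unevenly across 8 strata, each BG containing a
number of two-person households (HHs) drawn from an exponential
distribution with mean 450, rounded to an integer with floor 1. The
default stratum sizes (92, 91, 105, 92, 81, 91, 104, 96) were frozen once
from a seeded multinomial and are exposed in `pop_config()`; only the fact
that the split is uneven matters to the design.

Covariates, per individual:

* **Age** (years, integer). Each HH draws a mean age from
  N(40, 15²) truncated to [23, 69]; the two members' ages are uniform on
  the integers within ±10 years of that mean. Individual ages can
  therefore range from 13 to 79 — they are deliberately *not* re-truncated
  after the ±10 draw, since the HH-mean truncation is what defines the
  design's age targeting.
* **BMI** (kg/m²): N(29, 9²) truncated to [15, 63], independent across
  individuals.
* **Years between visits**: N(6, 0.5²) truncated to [3, 9].

Truncated normals are sampled by inverse-CDF on the truncated interval,
never by clipping, so the bounds are not atoms.

Random intercepts shared by all outcome models: a household effect
`h ~ N(0, 1)` common to both members, and a BG effect `b ~ N(0, 0.5²)`
common to the BG.

Association models (log odds-ratio coefficients, defaults in
`pop_config()`):

* exposure (insomnia):
  `logit P(Z=1) = log 0.109 + log(1.025)·bmi + log(1.019)·age`
* prevalent MCI at visit 2:
  `logit P(Y(a)=1) = log 0.003 + log(1.560)·a + log(1.018)·bmi + log(1.056)·age + h + b`
* hypertension, visit 1:
  `logit P = log 0.002 + log(1.065)·a + log(1.088)·bmi + log(1.082)·age + h + b`
* hypertension, visit 2:
  `logit P = log 0.001 + log(1.247)·a + log(1.082)·bmi + log(1.092)·age + log(1.098)·years + h + b`

Each outcome is drawn under both exposure levels (potential outcomes);
the observed outcome is `Y(Z) = Z·Y(1) + (1−Z)·Y(0)` exactly, row by row.
Under these defaults the generated population carries an insomnia
prevalence of ≈34%, MCI ≈10% and visit-1 hypertension ≈44–45%. The
random-intercept variance and the covariate heterogeneity push the
marginal prevalences above the naive expit of the mean linear predictor;
users targeting specific prevalences should use `calibrate_intercepts()`,
which solves for intercepts by monotone root-finding on the expected
(deterministic) prevalence.

Every variable family draws from its own named RNG substream keyed on the
seed, so a frame regenerates bit-identically and any one family can be
reproduced in isolation.

## The sampling design

Stage 1 keeps each BG independently with probability 0.25 (strata 1–4) or
0.60 (strata 5–8). Stage 2 keeps each HH in a retained BG independently
with probability `expit(−8 + 0.1 · max HH age)` (scenario 1), so
households with older members are strongly oversampled; both members of a
kept HH enter the sample. Inclusion probabilities multiply
(`p_ijk = p_i p_ij`), base weights are their inverses, and the analysis
weights (OSW) are base weights normalized to mean 1 within each sample.

Both stages use independent Bernoulli (Poisson-sampling) draws rather
than fixed-size without-replacement draws: this keeps each unit's
inclusion probability exactly the stated one, at the cost of a random
sample size. Scenario 2 replaces the age-dependent HH probability with a
single constant equal to the population mean of the scenario-1
probabilities, so the two scenarios have the same expected sample size and
differ *only* in whether the weights carry age information. (The precise
age-free design of the original secondary scenario is not fully
specified anywhere we could consult; matching expected sample sizes keeps
the comparison a pure test of weight–confounder correlation.)

## Estimators

Propensity scores come from a logistic model of exposure on the measured
covariates, bringing in the survey weights either as regression weights
(`osw_weighted`) or as an additional covariate (`osw_covariate`). Fitted
scores are clipped to [1e−6, 1−1e−6] as a positivity guard; clipping is
counted and essentially never triggers under the defaults.

* **PSM**: greedy 1:1 nearest-neighbour matching without replacement on
  the raw score difference. Exposed units are processed in descending
  score order; distance ties break to the lowest row index; no caliper.
  The written descriptions of the matching direction conflict in our
  sources (controls-to-treated versus all-treated-matched); we process
  exposed units — the standard ATT orientation in which every exposed unit
  is matched — and the direction is switchable in code by swapping the
  group labels. Effect models on the matched set are unweighted ("none"),
  OSW-weighted, or ISW-weighted (each matched control inherits its
  partner's OSW). ISW deserves a warning label: under an age-targeted
  design its weighted control group inherits weights that are correlated
  with the matching discrepancies, and its estimates are badly biased even
  when the confounder is fully measured — and even under a true null
  effect. The package implements it for completeness, not as a
  recommendation.
* **CEM**: covariates are coarsened (BMI at the clinical cutpoints
  18.5/25/30; age, years-between and — optionally — the OSW at
  within-sample quartiles/quintiles, the usual "meaningful cutpoints where
  available, quantiles otherwise" convention); bins lacking either
  exposure group are pruned; exposed keep weight 1 and controls are
  re-weighted so each bin's weighted composition matches the exposed
  group. Estimation weights are CEMW or CEMW×OSW.
* **Weighting**: IPTW (targets ATE) or odds weights (targets ATT), used
  alone or multiplied by OSW, on the full sample.

Incident-hypertension analyses restrict to individuals without observed
baseline hypertension *before* propensity estimation and matching,
mirroring how an analyst would build the risk set. Prevalent MCI uses
logistic regression (odds ratios); incident hypertension uses Poisson
regression with log link and a log-years offset (rate ratios).
Unadjusted models estimate marginal effects; adjusted models add BMI and
the confounder. Under "under-specification" the confounder is omitted
from *every* model — propensity, binning, and outcome.

## Variance estimation

All weighted analyses use a design-based Taylor-linearization (sandwich)
covariance written for this package: weighted score contributions are
aggregated to PSU (BG) totals, centered within their sampling stratum,
scaled by `n_h/(n_h−1)`, and sandwiched between the inverse expected
information — the standard first-stage with-replacement approximation,
with no second-stage finite-population correction. After matching or
pruning, rows keep their original stratum and BG labels; strata that lose
all but one PSU contribute the squared deviation of that PSU's total from
the overall mean (the "adjust" convention) with a warning. Unweighted
("no weights") PSM analyses use the model-based covariance, since no
design weighting is applied there. IRLS runs to a coefficient tolerance
of 1e−8 with at most 100 iterations; rank-deficient model matrices drop
aliased columns by QR pivoting; perfect separation raises an explicit
error rather than returning a degenerate fit.

## True effects and performance measures

True effects are computed once per population from the doubled frame (2N
rows, one per individual × exposure level) by ordinary unweighted ML —
the frame is the entire target population, so no design applies. ATE/CATE
use all rows, ATT/CATT the rows of observed-exposed individuals. The
incident-hypertension truth excludes rows with baseline hypertension
*under that row's exposure level* (per-row potential exclusion); a switch
(`baseline_exclusion = "observed"`) implements the observed-status
alternative, since either reading of the doubled-frame restriction is
defensible. Marginal fits use the closed-form aggregated MLE (identical
to the regression MLE, and cross-checked against brute-force odds/rate
ratios in the tests).

Bias is `mean(TE_hat − TE)` on the ratio scale and coverage the fraction
of replicate 95% Wald intervals containing TE, each accompanied by its
Monte-Carlo standard error; a method is flagged "robust" when coverage
stays within the closed band [0.93, 0.97] in scenario 1 and 2 under
correct specification and in scenario 1 under under-specification. The
band endpoints are treated as inside the band; the original convention is
not documented anywhere we could consult, and the closed choice is the
more conservative reading of "between".

## Sensitivity analyses

1. **Unmeasured confounder**: rerun with the confounder omitted
   everywhere, in both scenarios.
2. **Education correlation**: a new confounder replaces age in all four
   generating models while age keeps driving the sampling design.
   Education is a uniform draw on [min(age), max(age)] replaced by the
   individual's own age with probability `q`, with `q` solved numerically
   from the mixture moment identities so that cor(education, age) hits a
   target ρ ∈ {0.25, 0.5, 0.75} (verified by large-sample simulation in
   the tests).
3. **Prevalence grid**: intercepts recalibrated so exposure and outcome
   prevalences sweep 5–35% in steps of 10, robust methods only.

## Problem sizes and replication

The package's own acceptance checks run the full-size population
(752 BGs, ≈680k individuals, samples of ≈16–17k) with 300 replicate
samples per cell, which puts the Monte-Carlo standard error of a coverage
estimate near 0.013; comparisons against reference values use twice the
Monte-Carlo standard error. Replicates use independent seed substreams,
so results are independent of evaluation order. One population is held
fixed across replicates — sampling variability, not population
variability, is the object of study.

## What the simulation does not show

The generator emulates a two-stage area sample with equal-size households
and Bernoulli sampling; real multi-stage surveys add a third
within-household selection stage, nonresponse and poststratification
adjustments, and survey weights that are themselves modeled — none of
which are simulated. Outcome models are correctly specified logistic
models up to the omitted confounder; robustness here does not certify
robustness to functional-form misspecification. CEM's behaviour depends
on the number of matching strata relative to the sample size: with many
variables or small samples its pruned sample can shrink drastically, and
results from this harness (few coarsened variables, large samples) are
favourable to CEM in ways a small real analysis may not reproduce.
Replicate-weight variance methods (BRR, jackknife), calipered or optimal
matching, matching with replacement, and doubly-robust estimators are out
of scope.
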