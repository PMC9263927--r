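---
title: "Simulating a multi-arm multi-stage adaptive trial in motor neuron disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a multi-arm multi-stage adaptive trial in motor neuron disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design being simulated

`alsmams` simulates a multi-arm multi-stage (MAMS) placebo-controlled
platform trial in motor neuron disease (MND) with coprimary outcomes: the
rate of decline of the revised ALS Functional Rating Scale (ALSFRS-R, an
integer score from 0 to 48 that falls as disability progresses) and
overall survival. Several experimental arms share one contemporaneous
placebo arm. Each experimental-versus-placebo comparison passes through
three staged ALSFRS-R analyses with the option to stop randomising to
unpromising arms, followed by an event-driven survival analysis that is
tested inferentially only if the ALSFRS-R result was significant:

1. **Stage 1** — triggered when 50 participants per arm (excluding long
   survivors, i.e. participants more than 8 years from diagnosis at
   baseline) have at least 6 months of follow-up. The arm continues if the
   95% CI for its relative reduction in the rate of decline still includes
   (or exceeds) a 25% relative improvement — that is, if the upper CI
   bound is at least 25%. A CI of (−10%, 30%) continues; (−20%, 15%)
   drops.
2. **Stage 2** — at 100 per arm with 12 months of follow-up; continue if
   the benefit is significant at the pairwise one-sided 10% level
   (two-sided 20%).
3. **Stage 3** — the primary ALSFRS-R analysis at 150 per arm with 18
   months of follow-up, one-sided 2.5%.
4. **Survival** — analysed when 113 deaths have accrued in the placebo arm
   or stage-3 data collection is complete, whichever is later; log-rank
   comparison and covariate-adjusted Cox model, gatekept behind stage-3
   significance so that the pairwise one-sided error stays at 2.5%.

Randomising 177 per arm (`required_randomised(150, 0.10, 0.05)`) covers
the primary-analysis requirement of 150 after ~10% dropout and ~5% long
survivors, whose ALSFRS-R data are excluded (they remain in the survival
analysis). Distinct treatments are not multiplicity-adjusted against each
other; error control is pairwise.

The package turns each ingredient into testable code: a synthetic cohort
generator, Pocock–Simon minimisation, the hierarchical slope model, the
survival machinery, the decision rules, and a trial engine that estimates
operating characteristics by Monte Carlo.

## The data-generating model

Participant $i$ has a latent linear ALSFRS-R trajectory

$$y_{ij} = \beta_{0i} + \beta_{1i}\,(1-\rho_{a(i)})\,t_{ij} + \varepsilon_{ij},$$

with random intercept $\beta_{0i}\sim N(\mu_0,\sigma_0^2)$, random slope
$\beta_{1i}\sim N(\mu_1,\sigma_1^2)$ drawn on the placebo scale, residual
noise $\varepsilon_{ij}\sim N(0,\sigma_e^2)$, and $\rho_a$ the arm's
relative reduction in the rate of decline ($\rho=0.25$ removes a quarter
of the decline). The latent slope is drawn before randomisation and the
treatment factor $(1-\rho)$ applied at trajectory time, so randomisation
stays causally prior to the effect. Observations are rounded to the
nearest integer and then clamped to $[0,48]$ (rounding first: the
instrument is an integer scale). Observations stop at death — the
"hypothetical strategy" for death as an intercurrent event: the mixed
model treats post-death visits as missing, with no imputation.

Survival is exponential with the configured placebo median; an arm's
hazard ratio scales the hazard multiplicatively (implemented exactly by
dividing the placebo-scale time by the HR). Dropout is exponential,
calibrated so the probability of dropping out before month 18 equals
`dropout_fraction`, and is non-informative by default
(`informative_dropout_strength` links the dropout hazard to
faster-than-average decline if wanted). Dropout truncates ALSFRS-R visits
but not survival follow-up, which continues from medical records. Accrual
is a Poisson process at `accrual_rate` per month; visits follow the
two-monthly schedule exactly unless `visit_jitter_sd` is set.

### Default parameter values

The trial's own sample-size simulations were parameterised from a pooled
clinical-trials database whose fitted values are not public, so this
package's defaults are chosen once from typical published ALS trial
values, and every one is overridable in `scenario_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `placebo_slope_mean` | −1.0 | points/month | typical trial-population decline |
| `slope_sd` | 0.6 | points/month | marked between-patient heterogeneity |
| `intercept_mean`, `intercept_sd` | 38, 6 | points | trial-eligible baseline severity |
| `residual_sd` | 2.5 | points | test–retest noise of the instrument |
| `median_survival_placebo` | 24 | months | post-enrolment median in trial cohorts |
| `dropout_fraction` | 0.10 | by month 18 | design's planning value |
| `long_survivor_prob` | 0.05 | at baseline | design's planning value |
| `covariate_prevalences` | 0.70 / 0.15 | riluzole, NIV or gastrostomy | usage in incident trial cohorts |
| `accrual_rate` | 10 | /month | multi-site recruitment |
| `minimisation_prob` | 0.80 | | conventional "random element" |

Because the source parameterisation is unavailable, the published headline
operating characteristics (86% continuation beyond stage 2, 83% overall
power, 23%/2% stage-1 drop probabilities under null/25% effect) are
reproduced only qualitatively here; the package's acceptance surface
instead checks properties that do not depend on the unavailable values:
error control under the null, monotonicity in the effect size, parameter
recovery, and estimator equivalences.

## Minimisation

Allocation uses the Pocock–Simon range method over three binary baseline
variables — riluzole use, NIV and/or gastrostomy use, and long-survivor
status — with equal variable weights (the trial names the variables but
not the scoring rule; equal weights are the standard choice). For each
candidate arm the score is the sum over the participant's covariate
levels of the post-allocation range of ratio-adjusted counts across open
arms; the minimising arm is chosen with probability 0.80, otherwise one
of the other open arms uniformly. Long-survivor status is minimised on
even though long survivors are excluded from the primary ALSFRS-R
analysis set — the two facts are compatible, and the survival analysis
(which includes them) benefits from the balance. With
`minimisation_prob = 1` and constant covariates the procedure reduces to
strict count-balancing (per-arm totals never differ by more than one),
which the test suite checks, alongside a paired Monte Carlo comparison
showing smaller marginal covariate imbalance than simple randomisation.

## The analysis model

`fit_slope_model()` fits, by REML via `lme4`,

$$y_{ij} = \alpha_a + \beta_a t_{ij} + \gamma_1 \mathrm{ril}_i +
\gamma_2 \mathrm{niv}_i + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with per-arm fixed intercepts and slopes, main effects of the baseline
minimisation covariates (the long-survivor variable needs no adjustment
because long survivors are excluded from this analysis set), and
correlated random intercepts and slopes per participant (falling back to
independent random effects, with a warning, if the unstructured fit does
not converge). The arm-by-time coefficient $\beta_a-\beta_{\rm placebo}$
is the slope contrast $\Delta$; its Wald 95% CI uses a Normal reference,
which is adequate at stage sizes of 50 per arm and above. The arm main
effects matter: with a single shared intercept the classical equivalence
below fails.

The relative reduction is $\Delta / |\hat\beta_{\rm placebo}|$, with CI
endpoints obtained by dividing the $\Delta$ CI endpoints by the magnitude
of the estimated placebo slope (a plug-in ratio CI; a Fieller interval
would also be defensible but the plug-in form matches how the stage-1
examples are stated). If the placebo arm is not estimated to decline the
relative scale is undefined; an arm is then never dropped on the
undefined statistic (conservative), and the event is flagged.

Each stage's data cut includes *all* visits observed on or before the
trigger date — early enrollees contribute follow-up beyond the stage's
nominal horizon, matching an analysis "over the follow-up period".
Stage thresholds count calendar time since randomisation
(treatment-policy: discontinuers still count towards "completed k months").

### The two-stage fast path

`method = "twostage"` computes per-participant OLS slopes and regresses
them on arm and the same covariates. On balanced complete data this
reproduces the mixed-model contrast exactly (generalised least squares
with identical per-subject design matrices averages per-subject OLS
estimates, whatever the variance components), which the acceptance suite
verifies to six decimals. Under staggered accrual and dropout the two
estimators differ slightly — the two-stage route weights participants
equally rather than by information — but it is an order of magnitude
faster, which is what makes 1000-replicate operating-characteristic runs
of the complete design practical. `run_trial()` therefore defaults to
`analysis_method = "twostage"`; set `"reml"` for the full hierarchical
model.

## The trial engine

`run_trial()` simulates in calendar time. Stage $k$ for an arm fires at
the date when both that arm and its contemporaneous controls have
`stage_n[k]` non-long-survivor participants with `stage_months[k]` months
since randomisation; because entry times are continuous the binding group
reaches the threshold exactly at the trigger. Interim analyses are
instantaneous by default (`analysis_lag` configures a delay). A dropped
arm closes to new allocation and its share is redistributed by
renormalising the allocation ratio over the remaining open arms — the
natural behaviour of minimisation over the open set. The placebo arm
recruits while any experimental arm recruits, up to the cap per
contemporaneous comparison.

Arms can be added to the platform (`add_arm()`), opening at a configured
calendar month. An added arm is compared only against contemporaneous
controls — placebo participants randomised while it was open — and its
stage thresholds count from its own accrual. Arrivals during a period
with no open experimental arm are not randomised (recruitment pauses). No
multiplicity adjustment is applied across distinct treatments, so error
control is per comparison; the survival gatekeeping guarantees
replicate-by-replicate that survival significance never exceeds stage-3
significance.

`estimate_oc()` repeats `run_trial()` over independent replicates.
Per-replicate seeds are derived from the master seed by drawing an integer
seed vector under the master seed, so replicate $r$ is reproducible in
isolation; identical seed and configuration give identical results to the
byte.

## Numerical choices and degenerate inputs

* Gate boundaries are strict inequalities (`p < 0.10`, `p < 0.025`,
  upper CI bound `>= 25%`); the protocol text does not specify the
  boundary case, and a CI lying entirely above 25% continues (dominance).
* Scores are rounded before clamping; at the floor of the scale this
  matters, and the floor in turn flattens trajectories of severely
  affected participants — a real feature of the instrument. Because
  placebo participants reach the floor more often than treated ones, the
  floor attenuates the estimated relative reduction slightly under wide
  between-participant variances at the 18-month horizon (under the
  package defaults, by roughly one percentage point of relative
  reduction). The parameter-recovery oracle in the acceptance suite is
  therefore run with between-participant variances inside the regime
  where the floor is not binding: it is the estimator the oracle checks,
  not the instrument bound. With independent survival (the default), the
  floor is slightly over-represented relative to a real cohort, where
  rapid decline and death are correlated and floored observations are
  rarely made.
* Because of integer rounding, an *exactly* noise-free cohort is
  degenerate (all per-subject slopes identical, zero second-stage
  variance); deterministic-limit tests of the generator use
  integer-friendly grids, and deterministic-limit tests of the engine use
  a low-noise rather than zero-noise scenario.
* A fit with fewer than two distinct assessment times, or an arm with
  fewer than two estimable slopes, is signalled as a singular design, not
  silently coerced. Inside the engine an inestimable interim contrast
  continues the arm (never drop on an undefined statistic) and an
  inestimable final analysis is not significant.
* If accrual ends before a stage threshold can be met (possible in small
  custom scenarios), the analysis runs at the last attainable
  qualification date with the available participants.
* Cox fits use Efron tie handling; ties are measure-zero under the
  generator but arise in user-supplied tables.

## What the generator does and does not emulate

The generator reproduces the statistical structure the design analysis
assumes: linear mean decline with random intercepts and slopes, bounded
integer scores, exponential survival with proportional hazards,
non-informative dropout, staggered accrual, and independent binary
covariates. It does not emulate non-linear (e.g. sigmoidal) decline,
floor-driven informative missingness beyond the score floor itself,
correlation between decline rate and survival (survival and ALSFRS-R are
independent by default, and the joint case is deliberately not
implemented), covariate effects on the outcome (covariates are balance
variables only, so covariate adjustment is exercised but not stressed),
or seasonal/centre effects in accrual. Passing tests therefore certify
the design's behaviour *under its own working assumptions*, not
robustness to their violation.

## Problem sizes used in the checks

The packaged checks run the complete design at its true size — 1000
replicates of the full 531-participant trial for the null
error-control check, a three-point effect sweep at 150 replicates each,
and 500 mixed-model fits at stage-3 size for parameter recovery — with
smaller scenarios wherever a property is about mechanics rather than
power. These sizes give binomial Monte Carlo standard errors of about
0.5 percentage points on a 2.5% probability, small enough for the
3-standard-error acceptance bands used throughout.
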