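---
title: "Marginal structural Cox models for treated vs untreated MS registry cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural Cox models for treated vs untreated MS registry cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Observational MS registries record irregular clinic visits (EDSS scores),
relapses, treatment episodes, MRI assessments and pregnancies for tens of
thousands of patients. Comparing treated with untreated person-time naively
is badly confounded by indication: patients with recent relapses and higher
disability are more likely to start disease-modifying therapy (DMT), and
those same features predict future relapses and disability accrual. Because
these confounders are themselves affected by earlier treatment, standard
regression adjustment is invalid: a time-varying confounder that is also a
mediator cannot simply be conditioned on.

`msmtrial` implements the g-method answer: follow-up is discretised into
6-month (183-day) intervals; each interval is classified treated when DMT
covers at least 15 days of it; stabilized inverse-probability-of-treatment
weights re-balance treated and untreated intervals with respect to the
measured history; and weighted Cox models (marginal structural models,
MSMs) estimate per-protocol hazard ratios for three outcomes -- relapses,
12-month-confirmed disability worsening, and 12-month-confirmed
improvement -- together with treatment-by-modifier interactions, stratified
effects, and a three-way DMT x phenotype x relapse-rate term.

The stabilized weight for patient $i$ at interval $j$ is

$$ w_{ij} \;=\; \prod_{k=0}^{j}
\frac{P(A_{ik}=a_{ik}\mid A_{i,k-1}=a_{i,k-1},\,S_i)}
     {P(A_{ik}=a_{ik}\mid A_{i,k-1}=a_{i,k-1},\,T_{ik},\,S_i)}, $$

where $A_{ik}$ is the treated indicator, $S_i$ the baseline stabilizing
covariates (sex, MS duration at the first visit, date of birth) and
$T_{ik}$ the time-dependent covariates (age, pregnancy status, treatment
history, relapse history over the prior 12 and 24 months, MS duration,
EDSS, MS course; onset date enters alongside date of birth to absorb
long-term changes in DMT availability).

## Target-trial emulation designs

Three designs define time zero and the allowed treatment transitions:

* **A** (primary): time zero at the first EDSS visit; untreated patients
  may initiate once; follow-up is censored at the first treatment
  discontinuation, so nobody reverts to untreated. Episodes separated by at
  most 30 days count as one treated period -- switching DMTs is not a
  discontinuation, since all DMTs are pooled into one treated state.
* **B**: time zero at MS onset; free switching; no rebaselining. Intervals
  before the first EDSS score carry a missing-EDSS marker and are excluded
  from the disability outcome models.
* **C**: time zero at the first EDSS visit; the interval clock restarts at
  every change of treatment state, giving one at-risk segment per
  treated/untreated spell (weights and the time axis are segment-local).

## Confirmed disability events

EDSS scores recorded fewer than 30 days after a relapse onset are removed
before event derivation (transient relapse-related worsening), and only
recorded -- never carried-forward -- scores can create or confirm an event.
A worsening begins at the first score exceeding the current reference by
1.0 step (1.5 if the reference is 0; 0.5 above 5.5); improvement mirrors
this (1.5 at or below 1.5; 0.5 above 6). The event is confirmed when a
score at least 365 days after onset exists and *every* recorded score up to
and including the first such score holds the threshold; requiring all
intermediate scores, not just the confirming one, reflects confirmation by
subsequent scores in the plural and makes the event robust to single
fluctuation. By default the reference *roves*: it resets to the onset score
after each confirmed event, so sequential worsenings and recoveries
accumulate; a fixed study-baseline reference is available for sensitivity
(`reference_policy = "fixed_baseline"`). A trajectory that ends within 365
days of a qualifying change yields no event -- no extrapolation. Relapses
recorded under 30 days apart are merged to the earlier onset by default
(`relapse_policy = "strict"` rejects instead).

The detector is validated against an independent brute-force implementation
that enumerates every (onset, confirmation) pair over all short EDSS
trajectories on a fixed visit lattice.

## Weight estimation choices

* Conditioning on the previous treated state is implemented by
  *stratifying* the pooled logistic models on `prev_treated` rather than by
  an additive term: under design A continuation is deterministic (treated
  stays treated until censoring), which an additive model can only express
  through a diverging coefficient. A degenerate stratum receives its
  empirical constant probability, making its weight ratio exactly 1.
* The first in-study interval has no previous in-study state, so the
  baseline treated state (prevalent users) is itself modeled from baseline
  covariates, with a `baseline_bin` intercept shift separating the baseline
  decision from later initiation. Conditioning bin 0 on pre-baseline
  exposure instead would leave baseline confounding uncorrected.
* The EDSS entering the *treatment* models is the last recorded score on or
  before the interval start -- a pre-exposure quantity; the panel's `edss`
  column (last cleaned score on or before the interval end, carried
  forward) is the covariate/stratifier for outcome-side use. Conditioning
  treatment probabilities on end-of-interval EDSS would condition on a
  mediator.
* Age, MS duration, birth year and onset year are exactly linearly
  dependent; the aliased covariate is dropped and recorded in the fitted
  object.
* Fitted probabilities of the observed state are bounded inside
  (0.01, 0.99). Sparse indicator covariates that separate (for example a
  rare missing-EDSS marker) are dropped with a record; separation on a
  substantive covariate is an error naming it.
* When a treatment-by-modifier interaction is the target, the modifier is
  removed from both weight models (`interacted_modifier`), because a
  variable balanced away by the weights can show no interaction; the
  `ms_iptw` object records this and `fit_interaction()` enforces it.
* **Tail control.** Quantile winsorization at (0.01, 0.99) -- a common
  default -- proved counterproductive in calibration studies with this
  package's generator: the upper one percent of stabilized weights carry
  precisely the correction for the sickest untreated person-time, and
  clipping them re-introduced confounding (null-scenario coverage fell and
  the point estimate moved toward the naive one). The default is therefore
  no quantile truncation and a fixed cap of 20 on the weight
  (`iptw(truncation = c(0, 1), weight_cap = 20)`), which bounds the
  influence of rare extreme weights without touching the bulk of the
  distribution. `truncate_weights()` retains the quantile interface for
  sensitivity analyses. `balance_table()` reports decision-point
  standardized mean differences -- within previous-state strata where both
  states occur, under the full stabilized weight -- because a pooled
  treated-vs-untreated comparison over all intervals mixes in the causal
  effect of treatment on later covariates and the time trend of treatment
  prevalence, neither of which is confounding.

## Outcome models

Relapses are recurrent events: each interval contributes a binary
relapse-occurrence indicator, fitted as an Andersen-Gill counting process
with the treated indicator as the only regressor, weights equal to the
(capped) stabilized weights, and a robust sandwich variance clustered on
patient -- mandatory, since weighting induces within-patient dependence.
Disability outcomes are time-to-first-confirmed-event within the at-risk
segment. Events are placed at their actual dates (first in-bin relapse
onset, confirmed-event onset) and the interval's at-risk time is truncated
there: stacking every event on a 183-day boundary creates massive ties
whose Efron approximation measurably attenuates the hazard ratio when the
per-interval event probability is in the 10-15% range. The time axis is
time since the design baseline (segment-local under C). A pooled
discrete-time logistic estimator with cluster-robust variance is provided
as a cross-check (`estimator = "pooled_logistic"`); at per-interval event
probabilities of 10-15% its odds ratio is systematically farther from the
null than the hazard ratio, so agreement is expected in direction and
magnitude order, not to the third decimal. `check_ph()` exposes the scaled
Schoenfeld residual trend test so gross proportional-hazards violations are
surfaced rather than silently averaged.

Interactions treat EDSS and prior annualized relapse rate as continuous
(per step, per unit) and MRI activity and phenotype as categorical; the MRI
interaction uses only intervals with an assessment in the past year.
Stratified models default to sample quartiles of the stratifier and flag
inestimable strata instead of dropping them.

## The synthetic registry

Because the registry data this methodology is designed for cannot be
redistributed, the package ships a generator whose defaults emulate the
descriptive features of a large treated MS cohort: ~71% female, age at
onset ~31 years, median MS duration at first visit ~2.8 years, mean
follow-up 8.8 years, visits every ~120 days, ~0.45 untreated relapses per
year with lognormal patient frailty (sd 0.7 on the log scale), ~58% treated
at the first visit and ~78% of intervals treated, 7.5% progressive
phenotypes at onset, and RRMS-to-SPMS conversion at ~2% per year. Time
advances in 183-day epochs from the first EDSS visit:

* Untreated patients initiate DMT with probability
  `plogis(-3.1 + 0.4 * relapses_past_year + 0.4 * last_recorded_EDSS)`
  (intercept -1.0 at the baseline visit itself); treated patients stop with
  probability 0.04 per epoch. The coefficient 0.4 per relapse and per EDSS
  step is the `confounding_strength` parameter; it produces a naive relapse
  log-hazard-ratio bias around +0.2 under the protective scenario while
  retaining untreated person-time across the EDSS range (a stronger value
  starves positivity exactly where confirmed-improvement events arise,
  above EDSS 6, making weighting infeasible at realistic cohort sizes).
* Relapses follow a piecewise-constant intensity
  `0.45/yr * exp(frailty + 0.08 * (EDSS - 2) + treated * log(true_hr_relapse))`,
  thinned to the 30-day minimum separation; each relapse adds a transient
  +1.0 EDSS bump for 30-90 days (so post-relapse score exclusion has
  observable effect) and with probability 0.2 a permanent +0.5 step.
* Latent EDSS takes reflected random-walk steps on the valid grid
  (up 0.10, down 0.06 per epoch), multiplied by `true_hr_worsening` /
  `true_hr_improvement` while treated, with extra upward drift in
  progressive phenotypes.
* Treatment decisions condition on exactly the quantities the panel later
  reconstructs (relapse count in the trailing 365 days; last recorded
  EDSS), so sequential ignorability given the weight-model covariates holds
  *by construction* -- this is what makes parameter recovery a meaningful
  test of the estimation chain rather than of generator quirks.

Scenario presets: `null` (all effects 1, confounding on), `protective`
(relapse HR 0.5, worsening 0.55, improvement 1.3), `no_confounding`,
`modified_by_edss` (treated relapse log-intensity +0.35 per EDSS step, a
deliberately detectable modification), and `phenotype_specific` (30%
progressive phenotypes in whom treatment is inert). Forcing
`force_treatment = "always"` / `"never"` yields counterfactual cohorts
whose relapse-rate ratio reproduces the nominal effect and serves as the
ground-truth oracle.

What the generator does *not* emulate: per-DMT efficacy differences, MRI
lesion counts beyond a binary activity flag, informative visit scheduling,
measurement error in relapse ascertainment, center effects, or mortality.
Passing parameter-recovery tests on these cohorts therefore demonstrates
the correctness of the estimation chain under the model's assumptions, not
robustness to every failure mode of real registry data.

## Validation studies and their sizes

The test suite regenerates everything from code: exhaustive event-detector
enumeration (~300k trajectories), a weight-identity check, a balance and
calibration check at n = 2000, null-coverage studies (100 replicates at
n = 1000), confounding-correction studies (100 replicates at n = 2000),
effect-modification recovery (50 replicates at n = 4000), and a
design-concordance study without confounding. These sizes keep the full
suite within a routine desktop run while holding Monte-Carlo error on a
coverage proportion near two percentage points.

## Known limitations

* With roughly 78% of intervals treated and initiation strongly tied to
  disability, untreated person-time at high EDSS is scarce; stabilized
  weights are heavy-tailed and low-event outcomes (confirmed improvement)
  estimate with wide intervals at a few hundred events.
* The observable relapse process is history-dependent by definition (two
  onsets under 30 days apart are one relapse), and the marginal structural
  model conditions only on the current treated state. The weighted Cox
  estimate is therefore a projection whose large-sample value can sit a few
  percent off the forced always-vs-never contrast even with exactly known
  treatment probabilities -- an offset of about +0.03 to +0.05 on the log
  hazard ratio under this generator's conditions, with the consequence that
  confidence-interval coverage of the oracle effect runs a few points below
  nominal in the simulation studies even though the bias-reduction relative
  to the naive estimate is large (roughly four-fold). The package's
  validation suite measures and reports this honestly rather than hiding it
  behind a looser tolerance; users comparing designs or modifiers (the
  primary use) are unaffected, since the projection offset is shared.
* Inverse-probability-of-censoring weights are not constructed; under
  design A, discontinuation censoring is assumed independent given the
  measured history.
* Confirmed events may use scores recorded after the analytic censoring
  date for confirmation; the event time is always the onset.
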