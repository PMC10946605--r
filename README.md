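# msmtrial

Marginal structural Cox models for target-trial emulation in multiple
sclerosis (MS) registries: estimating the per-protocol effect of
disease-modifying therapy (DMT) on relapses and on 12-month-confirmed
disability worsening and improvement, from irregular longitudinal patient
records, in the presence of confounding by indication.

The package is aimed at biostatisticians and pharmaco-epidemiologists
working with registry-style MS data (visit-level EDSS scores, relapse
onsets, treatment episodes, MRI activity, pregnancies). Sicker patients are
more likely to start therapy, and the confounders (recent relapses,
disability) are themselves affected by earlier treatment, so naive and
covariate-adjusted comparisons are both invalid. The package implements the
g-method pipeline:

1. **Eligibility**: follow-up of at least one year, at least three EDSS
   scores with none more than a year apart, complete minimum dataset;
   follow-up trimmed to the span from first to last EDSS score; the
   relapsing cohort is censored at conversion to secondary progressive MS.
2. **Confirmed events**: EDSS scores under 30 days after a relapse are
   discarded; disability worsening/improvement requires a
   reference-dependent step (worsening: 1.0; 1.5 from EDSS 0; 0.5 above
   5.5) held by *every* subsequent recorded score through at least 365
   days, with a roving reference by default.
3. **Panels**: follow-up cut into 183-day bins; a bin is "treated" when DMT
   covers at least 15 days of it; time-dependent covariates are attached
   per bin. Three emulation designs: **A** (time zero at first EDSS visit,
   censoring at first discontinuation), **B** (time zero at MS onset, free
   switching), **C** (rebaselining at every treatment transition).
4. **Stabilized weights**: pooled logistic models of the per-bin treated
   state, conditioned on the previous state by stratification, give

   w_ij = prod_{k=0..j} P(A_k | A_{k-1}, S) / P(A_k | A_{k-1}, T_k, S),

   with S the baseline stabilizing covariates (sex, MS duration at first
   visit, date of birth) and T_k the time-dependent history (age,
   pregnancy, treatment history, 12/24-month relapse rates, MS duration,
   EDSS, MS course, onset date). A modifier under interaction study is
   excluded from both models.
5. **Inference**: weighted Cox models with robust patient-clustered
   variance — recurrent per-bin relapse events (Andersen–Gill),
   time-to-first confirmed disability events — plus treatment-by-modifier
   interactions, stratified hazard ratios, and the three-way
   DMT x phenotype x relapse-rate term.

Because the registries this methodology targets are not redistributable,
the package includes a synthetic-registry generator (`simulate_cohort()`)
with known ground-truth hazard ratios and genuine confounding by
indication, so the whole chain is validated by parameter recovery. See the
methods vignette (`vignettes/msmtrial-methods.Rmd`) for the model, the
generator, and every numerical choice.

## Worked example

```r
library(msmtrial)

scenario <- default_scenarios(n_patients = 1000)$protective  # true relapse HR 0.5
scenario$seed <- 42L
registry <- simulate_cohort(scenario)
registry
#> <ms_registry> 1000 patients; 26264 EDSS visits; 5712 relapses; 1150 treatment episodes

cohort <- filter_eligible(registry, "relapsing")
events <- derive_events(cohort)
panel <- build_panel(cohort, "A", events)
panel
#> <ms_panel design A> 11274 bins, 909 patients, 73% treated bins, 1826 relapse bins,
#>   202 worsening / 101 improvement onsets

weights <- iptw(panel)
weights
#> <ms_iptw> 11274 bins; stabilized weights mean 0.971 (sd 0.539), range [0.177, 21.864]

fit_msm(panel, weights, "relapse")
#> MSM Cox model, outcome 'relapse', design A
#>   Overall                                HR  0.500  (95% CI 0.422-0.592)  p=1.2e-15
#>   909 patients, 1826 events

fit_msm(panel, NULL, "relapse")   # naive, confounded benchmark
#> MSM Cox model, outcome 'relapse', design A
#>   Overall                                HR  0.673  (95% CI 0.588-0.771)  p=1.1e-08
#>   909 patients, 1826 events (unweighted)

balance_table(panel, weights)
#>       covariate smd_unweighted smd_weighted
#> 1 arr_prior_12m      0.3267851  -0.02533598
#> 2 arr_prior_24m      0.3167129  -0.03556923
#> 3          edss      0.5776856  -0.02208818
#> 4           age     -0.1365977  -0.13915361
#> 5   ms_duration     -0.2770941  -0.25531329
```

The generator planted a true relapse hazard ratio of 0.5 with strong
confounding by indication: the naive comparison is biased to 0.67, while
the weighted (MSM) estimate recovers 0.50 and the decision-point
standardized mean differences of the indication confounders (prior relapse
rate, EDSS) collapse from 0.33/0.58 to about 0.03 after weighting. (Age and
MS duration are retained baseline-linked differences the stabilized
numerator deliberately leaves in place.)

Interaction and stratified analyses follow the same pattern; note the
weights must be re-estimated with the modifier excluded:

```r
w_edss <- iptw(panel, interacted_modifier = "edss")
fit_interaction(panel, w_edss, "relapse", "edss")
fit_stratified(panel, w_edss, "relapse", "edss")     # quartile strata, forest plot via plot()
```

`run_analysis(analysis_config(...))` chains every stage with stage-level
logging, writes all artifacts (panel, weights, results, diagnostics, a text
forest report) and an md5 manifest, and is deterministic given the seed.

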