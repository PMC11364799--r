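# stagecraft

Construction and evaluation of multi-cutoff prognostic staging systems from
continuous tumor-size measurements under right-censored survival.

## The problem

Solid-tumor T-staging often dichotomizes a continuous size measurement —
for oral tongue carcinoma, the depth of invasion (DOI, mm) — into ordinal
risk groups at fixed cutoffs (the 8th-edition AJCC convention uses
pathological DOI at 5 and 10 mm). When the same quantity is measured
preoperatively on MR imaging (radiological DOI, rDOI), it carries a
systematic positive bias and extra noise relative to pathology, and the
optimal cutoffs for a *radiological* staging system need not coincide with
the pathological ones. `stagecraft` implements the full workflow for
deriving and defending such a staging system:

1. **Measurement agreement** — Pearson correlation with concordance labels,
   Bland–Altman bias and 95% limits of agreement
   (`bias ± 1.96·sd(differences)`), and two-way random-effects
   ICC(2,1) for intra-/inter-observer reproducibility (threshold 0.75).
2. **Multiple imputation** — fully conditional specification with
   predictive mean matching for missing measurement columns, the censored
   outcome entering the predictor set as (event, Nelson–Aalen cumulative
   hazard); Rubin's rules for pooling Cox estimates.
3. **Confounder selection** — univariate screening (p < 0.10) followed by
   bidirectional stepwise Cox by AIC, with clinically forced-in terms.
4. **Cutoff-count selection** — Cox fits on restricted cubic splines of the
   measurement at 3/4/5 knots; the knot count with the lowest AIC (ties
   resolved to parsimony) maps to `knots − 1` cutoffs.
5. **Exhaustive cutoff search** — for every ascending cutoff tuple on a
   0.5-mm grid spanning the 5th–95th percentile, fit the
   confounder-adjusted Cox model `Surv ~ stage + confounders` and keep the
   admissible tuple (each group ≥ 10% of subjects) maximizing the partial
   log-likelihood.
6. **Scheme evaluation** — Harrell's C-index with paired-bootstrap
   comparison, decision curve analysis at 36/60 months (Kaplan–Meier
   censoring adjustment), and four staging quality criteria (hazard
   consistency, hazard discrimination, sample-size balance, outcome
   prediction against a log-rank recursive-partitioning benchmark).

Because no patient-level data ship with the package, a first-class
**synthetic cohort generator** reproduces the statistical structure the
analysis assumes: a truncated-normal latent depth (8.3 ± 4.8 mm), biased
noisy per-sequence measurement columns (≈ 3–3.4 mm bias, ≈ 4 mm noise),
correlated clinicopathological covariates, a Weibull proportional-hazards
event process (per-mm HR 1.08, or a step function of depth), independent
administrative censoring, per-sequence missingness, and seeded observer
replicates. Every stochastic stage derives an independent stream from one
master seed, so identical configurations reproduce byte-identical reports.

## Worked example

```r
library(stagecraft)

cfg <- synthetic_config(
  n_subjects = 600, seed = 42,
  censor_dist = c(min = 60, max = 180),
  step_hazard = list(cutoffs = c(8, 12), log_hrs = log(c(1, 3.5, 4.5))))
cohort <- generate_cohort(cfg)

search <- exhaustive_search(cohort, "pDOI",
                            confounders = c("age", "sex_female", "pN_stage"),
                            n_cutoffs = 2)
search$scheme
#> <staging_scheme> pDOI: rT1 (<= 8 mm), rT2 (<= 13 mm), rT3 (> 13 mm)

ev <- evaluate_scheme(search$scheme, cohort,
                      comparator = staging_scheme("pDOI", c(5, 10)),
                      n_boot = 200, seed = 1)
ev
#> <scheme_evaluation> n = 600
#>   C-index: 0.658 vs 0.632 (delta +0.026, p = 0)
#>   quality criteria (scheme vs comparator):
#>     hazard_consistency : 0.07 +/- 0.03 vs 0.19 +/- 0.03
#>     hazard_discrimination : 0.55 +/- 0.05 vs 0.61 +/- 0.05
#>     balance : 0.25 +/- 0.02 vs 0.19 +/- 0.02
#>     outcome_prediction : 100.95 +/- 2.50 vs 64.71 +/- 8.81
```

The cohort was generated with true change-points at 8 and 12 mm and group
hazard ratios (1, 3.5, 4.5). The adjusted search recovers the first
change-point exactly and places the second within 1 mm of truth — typical
behavior, since the second hazard jump (4.5/3.5 ≈ 1.29) carries far less
information than the first. Against the conventional 5/10-mm comparator
the derived scheme shows a higher concordance index, lower (better)
within-stage heterogeneity, more stage-level hazard spread, and a larger
share of the survival-tree benchmark's explained likelihood; group sizes
are slightly less balanced (0.25 vs 0.19, lower is better) because the
derived cutoffs sit higher in the depth distribution.

The full workflow — agreement, imputation, confounder selection, cutoff
search, evaluation, artifact files — runs as one call:

```r
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = 42,
                                    out_dir = "staging_out"))
```

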