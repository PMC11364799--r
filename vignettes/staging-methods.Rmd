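---
title: "Methods: deriving and evaluating multi-cutoff staging systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and evaluating multi-cutoff staging systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecraft)
```

`stagecraft` turns a continuous, imperfectly measured tumor-size variable —
prototypically the radiological depth of invasion (rDOI, mm) of an oral
tongue carcinoma measured on several MR sequences — into an ordinal
prognostic staging system for overall survival, and then defends that
system with a multi-criteria evaluation battery. This vignette records the
models, the tunable parameters, the numerical conventions, and the design
decisions that were genuinely open, in the order the pipeline runs them.

## The synthetic cohort model

No patient-level data ship with the package; all tests and worked examples
run on cohorts drawn by `generate_cohort()`. The generator encodes the
statistical structure the analysis stages assume:

* **Latent depth.** Pathological DOI $D_i$ is truncated normal,
  default mean 8.3 mm, sd 4.8 mm on $[0, 36]$ mm — the distribution
  reported for surgical oral-tongue cohorts. Truncation at 0 shifts the
  *realized* moments slightly upward (to roughly 8.8 ± 4.4 at the
  defaults); configuration parameters refer to the untruncated normal.
* **Measurements.** Each radiological column reads its anchor (depth for
  `rTT_*`/`rDOI_*`; a latent in-plane diameter
  $L_i = 4 + 2.1\,D_i + \varepsilon$ for `LD_*`) plus a per-sequence
  additive bias and Gaussian noise, floored at 0.1 mm. Defaults follow the
  radiology–pathology disagreement typically reported for this disease:
  bias ≈ 3–3.4 mm, noise sd ≈ 3.9–4.1 mm for the depth columns. Ulcerative
  morphology multiplies the noise sd by 1.5 (the mechanism behind the
  weaker agreement in ulcerated lesions is unobservable; multiplicative
  noise inflation is the simplest device that reproduces it), exophytic by
  0.8.
* **Outcome.** Survival times follow a Weibull proportional-hazards model,
  $S(t \mid x) = \exp\{-(t/\lambda)^{k} e^{\eta}\}$, with shape $k = 1.1$
  and scale $\lambda = 230$ months for a subject at covariate means. The
  linear predictor $\eta$ adds a depth term — per-mm log hazard ratio
  $\log(1.08)$ by default, or a step function of depth when a
  `step_hazard` is configured — to centered covariate effects with
  prevalences and moderate log-HRs typical of a non-metastatic pT1–3
  cohort. A parametric baseline is required for closed-form sampling; the
  analysis stages remain semiparametric Cox throughout.
* **Censoring.** Administrative, uniform on 12–120 months by default.
  Together with the baseline these defaults were calibrated once to a
  cohort profile of roughly 25% deaths, 5-year overall survival near 75%,
  and median follow-up near five years.
* **Missingness.** Per-sequence MCAR by default (3–12%, sagittal worst);
  a MAR mechanism conditioning on any covariate is available
  (`prob`, `delta` on the logit scale). Derived row-maximum columns
  (`rTTmax`, `rDOImax`, `LDmax`) are recomputed after cells are punched.
* **Replicates.** `generate_observer_replicates()` re-reads a random 10%
  of subjects; a replicate equals the original measurement plus reading
  noise (sd 1.2 mm by default), emulating an intra-observer repeat and an
  independent second observer.

One master seed drives everything through independent child streams per
stage, so toggling one stochastic stage never perturbs another's draws and
identical configurations give byte-identical artifacts.

What the generator does **not** emulate: anatomy or image formation,
informative censoring, measurement error that depends on depth itself,
correlated missingness across sequences within a subject, and reader
learning effects. Tests passing on these cohorts therefore certify the
statistical machinery, not the clinical performance of any particular
imaging protocol.

## Agreement analytics

`pearson_agreement()` labels correlations at the conventional
0.8/0.6/0.4 thresholds; subgroups with fewer than three complete pairs are
reported as missing rather than erroring. `bland_altman()` uses the n−1
denominator and exact limits `bias ± 1.96·sd`. For observer
reproducibility the ICC form is not dictated by the workflow itself; we
default to the two-way random-effects, absolute-agreement, single-rater
form ICC(2,1), because raters/occasions are best treated as random and a
systematic offset between readers should count against reproducibility. A
consistency form ICC(3,1) is available. Confidence intervals follow the
McGraw–Wong F constructions; negative point estimates are clipped to zero
and flagged. The reproducibility threshold is 0.75.

## Imputation

Missingness is confined to measurement columns by construction (covariates
arrive complete). `fcs_impute()` runs fully conditional specification with
predictive mean matching: each incomplete column is regressed on the other
measurement columns, numerically coded covariates, the event indicator and
the Nelson–Aalen cumulative hazard at the observed time (the standard
encoding of a censored outcome for imputation). A Bayesian draw of the
regression coefficients produces predictions for missing rows; each is
matched to its five nearest observed predictions and one donates its
value. Defaults `m = 5` chains × 10 cycles are common FCS practice; none
of these values is dictated by the workflow, and all are arguments.
Columns more than 80% missing are dropped from predictor sets (with a
warning) but still imputed; an all-missing column is an error. Downstream
Cox estimates pool across completed tables by Rubin's rules with the
classical degrees of freedom.

The pipeline runs the cutoff search on the first completed table rather
than per-table with a pooled vote: cutoff selection is a decision, not an
estimate, and the imputation-robustness property we test is that moderate
MCAR missingness leaves the selected scheme unchanged relative to the
complete-case subset.

## Survival primitives

Kaplan–Meier, log-rank, and Cox fitting delegate to the `survival`
package; the wrappers fix the conventions the pipeline relies on. Ties are
handled by Breslow's method by default (adequate at mm-grid granularity;
Efron available by flag). Five-year overall survival is read from the
group Kaplan–Meier curve as $S(60\text{ months})$ with last-value
carry-forward beyond the final observed time. The restricted cubic spline
basis is the Harrell truncated-power parameterization (linear beyond the
boundary knots, $k$ knots → $k-1$ columns, knots at the standard
quantiles). Harrell's C counts usable pairs under right censoring with
prediction ties scoring one half; the paired comparison of two C-indices
bootstraps subjects (default 1000 resamples) and reports a two-sided
bootstrap p — chosen over jackknife variance for transparency: the test
statistic's null distribution is exactly the resampled difference.

Confounder selection mirrors the two-stage "univariate then multivariate"
convention: candidates pass a univariate Wald screen at p < 0.10, then a
bidirectional stepwise search by AIC; clinically mandated covariates
(default: sex and betel-liquid use, when present) are forced into every
model. Exact entry/stay thresholds are not canonical anywhere; AIC with a
0.10 screen is declared here once and exposed as arguments.

## Cutoff-count selection and the exhaustive search

The number of cutoffs comes from spline flexibility: Cox fits on RCS bases
with 3, 4, 5 knots, lowest AIC wins, and knot counts within ΔAIC = 2 of
the optimum resolve to the smallest (the conventional equivalence band).
The flexibility-to-cutoff map is `knots − 1`: three knots support one bend
on each side of the median — the natural analogue of two cutoffs and three
groups. On smooth (linear log-hazard) cohorts this selects three knots
essentially always. On cohorts with *strong* step effects (hazard ratios
jumping 1 → 3.5 → 4.5) the AIC often prefers 4–5 knots, because extra
knots genuinely buy likelihood against a steep double step; the
three-knot expectation holds there only for milder steps. We keep the
parsimony band at the conventional 2 rather than widening it to force the
three-knot answer.

The search itself is explicit enumeration — the tractable and auditable
choice at this scale (a 0.5-mm grid over the 5th–95th percentile gives at
most a few thousand Cox fits per measurement). The objective is the
adjusted partial log-likelihood (equivalently AIC at fixed df), the
natural Cox criterion implied by an AIC-based pipeline; an adjusted
C-index objective is available. Admissibility requires every group to hold
at least 10% of subjects (well below the ~30% smallest group a published
staging would report, but enough to exclude degenerate fits). The boundary
convention is "value ≤ cutoff belongs to the lower group". Because an
exhaustive search is a minimum-p device, the selected scheme is never
defended by its search criterion: it is re-evaluated with
confounder-adjusted Cox models and bootstrap C-index comparison.

A localization caveat measured on generator cohorts, worth recording: with
$n = 600$ and the canonical step pattern, the first change-point (hazard
jump ×3.5) is found to within half a millimetre in ~90% of replicates,
but the second (jump ×1.29) has a profile-likelihood argmax with sampling
sd near 1.5 mm, so joint half-millimetre recovery of both cutoffs occurs
in only roughly half of replicates — at any censoring level up to
near-complete follow-up. Sharp joint recovery of weak second change-points
at these sample sizes is beyond what the likelihood contains.

## The evaluation battery

`evaluate_scheme()` compares a candidate scheme with a comparator (default:
the 5/10-mm pathological-depth convention) on complete pairs:

* **C-index** of the stage-factor Cox linear predictor, with the paired
  bootstrap difference.
* **Staging quality criteria**, each normalized to a known range and
  bootstrapped (mean ± sd over resamples) because their sampling
  distributions are otherwise opaque. The four metrics follow the familiar
  names — hazard consistency, hazard discrimination, sample-size balance,
  outcome prediction — but their exact formulas are declared here and are
  a re-implementation of the published intent, not a clone of any
  reference tool: consistency is the size-weighted mean absolute deviation
  of sub-bin (within-stage median split) 60-month mortality from the stage
  mean, normalized by its maximum 0.5; discrimination is one minus the
  range of stage-level 60-month mortalities (lower = better, matching the
  published direction); balance is
  $\sum_g |n_g/n - 1/G| \,/\, 2(1-1/G)$, exactly zero for equal groups;
  outcome prediction is the stage factor's Cox likelihood-ratio gain as a
  percentage of the gain of a survival-tree benchmark partition. The
  benchmark tree is grown once on the full data and held fixed across
  bootstrap resamples, so the ± term reflects sampling of the metric, not
  tree instability. Under this likelihood-ratio definition, merging two
  stages can never increase outcome prediction (nested models), a property
  the tests verify.
* **Decision curves** at 36 and 60 months, with the true/false-positive
  fractions among high-risk subjects estimated by Kaplan–Meier at the
  horizon to respect censoring; risks are the per-group KM event
  probabilities. Treat-all and treat-none references included.

The survival tree (`rpa_tree()`) is a greedy log-rank splitter: every
candidate threshold of every predictor is scored by the two-sample
log-rank statistic; the winning split must pass a Bonferroni-adjusted
p < 0.05 (adjusted by the number of candidates examined at that node) with
both children ≥ 20 subjects, up to depth 3. These stopping rules are this
package's own; the tree replaces external web tools in the evaluation
battery.

## Numerical conventions and degenerate inputs

All sds use the n−1 denominator. Cutoffs are strictly ascending; every
non-missing value maps to exactly one group and missing values are
excluded from summaries with their count reported. Constant covariates are
dropped from Cox fits with a warning; separation or non-convergence
surfaced by the fitter marks the fit as flagged. A constant ratings matrix
is a degeneracy error for the ICC; negative ICC estimates clip to zero
with a flag. Zero-variance vectors make Pearson correlation an error, not
NA. Grid construction rounds the lower end up to the step so cutoffs land
on interpretable half-millimetre values.

## Problem sizes used in tests

The shipped tests run on cohorts of 50–900 subjects for structural and
behavioral checks, 50 replicates of $n = 600$ for cutoff recovery, 20
replicates of $n = 5000$ for per-mm hazard-ratio recovery, and $n = 2000$
two-rater panels for ICC recovery — sizes at which Monte-Carlo error is
small relative to each test's tolerance. The per-mm recovery experiment
switches covariate effects off so that the univariate Cox estimand equals
the configured parameter; with independent covariate effects active the
marginal univariate hazard ratio is attenuated by non-collapsibility
(to ≈ 1.065 at the defaults) — a property of the estimand rather than an
estimation failure, and worth remembering when comparing published
univariate and adjusted per-mm hazard ratios.

## Known limitations

* The generator's measurement error is additive Gaussian on the mm scale
  and independent of depth; real radiological error is plausibly
  heteroscedastic.
* The exhaustive search fixes the number of cutoffs before searching;
  joint selection of count and locations would require a different
  multiplicity treatment.
* The staging quality criteria are one defensible operationalization of
  the published names; absolute values are not comparable across
  implementations, only the scheme-vs-comparator contrasts within one.
* Decision-curve risks come from per-group KM estimates and therefore step
  with the staging; model-based smoothing is out of scope.
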