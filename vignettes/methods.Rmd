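---
title: "Methods: nonlinear folate/B12 dose-response and biomarker subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear folate/B12 dose-response and biomarker subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folatecog)
```

## The scientific question

Folate and vitamin B12 are one-carbon-metabolism nutrients long implicated
in cognitive aging: deficiency impairs the methionine synthase reaction and
raises homocysteine, while chronic excess (largely from fortification and
supplements) has been suspected of harming cognition, particularly when
B12 is low. If both tails are harmful, the dose-response between a
biomarker of folate/B12 status and a cognitive test score should be an
inverted U: scores rise with the biomarker up to some concentration and
decline beyond it. Two practical questions follow. First, where is the
turning point for each biomarker and each cognitive domain? Second, do
biomarker profiles define clinically meaningful subgroups of older adults?

`folatecog` implements the full analysis pipeline for these questions on
participant-level cohort data: four exposures (RBC folate, serum total
folate, 5-methyltetrahydrofolate, serum vitamin B12) crossed with four
cognitive outcomes (CERAD Word Learning, CERAD Delayed Recall, Animal
Fluency, Digit Symbol Substitution).

## Cohort derivation

Analysis variables are derived per participant:

* **eGFR** by the 2009 CKD-EPI creatinine equation (inputs: creatinine in
  mg/dL, age, sex, Black race). Renal function confounds B12/MMA levels, so
  participants with eGFR < 60 mL/min/1.73 m² are excluded.
* **Low vitamin B12 status**: serum B12 < 148 pmol/L, or MMA > 210 nmol/L,
  or both. All thresholds in the package are strict inequalities, as
  conventionally printed.
* **Cognitive impairment flags**: CERAD-WL < 17 together with CERAD-DR < 5;
  AF < 14; DSST < 34.
* **Dietary folate equivalents**: `DFE = food folate + folic acid / 0.6`
  (µg); synthetic folic acid is the more bioavailable form.

Eligibility keeps participants aged 60+, with complete required fields,
eGFR ≥ 60, and no stroke history. The published criteria do not state an
order of application, so the package fixes one (age, completeness, eGFR,
stroke) and assigns each excluded record exactly one reason; this makes the
audit counts reproducible and the filter idempotent. Completeness is
defined over all modelled fields (demographics, comorbidities, creatinine,
the five biomarkers other than UMFA, the dietary folate variables, and the
four scores). No imputation is performed: the analysis is complete-case.

## Spline dose-response models

Each score is regressed on each biomarker with a 3-knot restricted cubic
spline at the 10th/50th/90th empirical percentiles of the exposure
(quantiles by linear interpolation of order statistics, `type = 7`; the
convention is fixed and documented because published analyses rarely state
one). The basis is the truncated-power restricted form normalized by
`(t3 - t1)^2`, which leaves exactly one non-linear column, so the
likelihood-ratio test of non-linearity has one degree of freedom:

`LR = n log(RSS_linear / RSS_spline) = 2 (ll_spline - ll_linear) ~ chi-square(1)`.

Models adjust for age and age², sex, race/ethnicity, marital status,
education, smoking, drinking, hypertension, hyperlipidemia, diabetes, eGFR,
and the four folate intake variables. Because DFE is by definition a linear
combination of food folate and folic acid, the adjusted design is exactly
rank-deficient; `build_design()` drops aliased columns (keeping the
leftmost) and records them in the fitted object rather than failing, which
reproduces what `lm()` would do silently. Zero-variance columns (e.g. a
single-sex stratum) are dropped with a warning.

The fitted curves are population-average (g-computation) predictions: each
grid value is substituted into every observed covariate row and the
predictions averaged; the band is `estimate ± 1.96 SE` with the
delta-method SE `sqrt(x̄' V x̄)`. Fixing covariates at their means is also
available (`at = "means"`); for a linear model the two differ only through
non-linear covariate terms (here age²), and population-average is the
default because it describes the analysed population rather than a
synthetic mean individual. The grid never extrapolates beyond the observed
exposure range.

Subgroup analyses refit the whole pipeline within low and normal B12
strata; effect modification is tested by adding products of the two spline
columns with the binary status (LR test, 2 df). No multiplicity correction
is applied across the 16 marker-by-test combinations; the analysis uses a
flat two-sided 0.05 rule, and the package reports raw p-values.

## Change-point estimation

Where non-linearity is present, the turning point is located with a
two-line continuous piecewise linear (hinge) model
`y = b0 + b1 x + b2 (x - c)+ [+ covariates]`, fitted by exhaustive profile
likelihood: every candidate `c` is tried and the candidate minimizing the
RSS (maximizing the Gaussian likelihood) is kept, with the full profile
retained for plotting. Numerical choices:

* Candidates are the unique observed exposures inside the 5th-95th
  percentile window with at least 10 observations on each side; untrimmed
  extremes produce degenerate one-sided fits.
* Ties in RSS are broken toward the smaller candidate, for determinism.
* Continuity at `c` is imposed (a dose-response is continuous); two
  disconnected lines are not considered.
* Covariates are included by default, matching the adjusted spline models;
  the unadjusted variant is a toggle since the published description does
  not state which was used.
* The profile log-likelihood is reproducible from the profile RSS via
  `-(n/2)(log(2 pi RSS / n) + 1)`; a perfect fit floors RSS at
  `machine-epsilon x (n-1) Var(y)` before the logarithm.

The estimator shifts equivariantly with the exposure, and on noiseless
two-line data recovers the true change point exactly whenever it lies on
the candidate grid. No confidence interval for `c` is claimed beyond the
profile itself.

## Biomarker subgrouping

The four markers are min-max normalized to [0, 1] and clustered with
K-means. "10,000 iterations" in the published description is interpreted
as 10,000 independent random restarts of Lloyd's algorithm (one Lloyd run
converges in far fewer passes); the package uses k-means++ seeding, keeps
the best within-cluster sum of squares, caps Lloyd at 300 iterations with
relative tolerance 1e-6, and re-seeds an emptied cluster from the farthest
point. The restart count is configurable; desk-scale analyses here use
10-100 restarts, which on well-separated data reach the same optimum.

K is selected over 2..8 by the Calinski-Harabasz score
`[B/(K-1)] / [W/(n-K)]`, ties to the smaller K. Cluster reliability uses
case-resampling bootstrap (full n, with replacement): each resample is
re-normalized and re-clustered at the same K, each original cluster is
matched to the resample cluster of maximal Jaccard similarity computed on
the records present in the resample, and the per-cluster mean Jaccard and
dissolution count (Jaccard < 0.5) over B resamples are reported
(`clusterboot`-style). Re-normalizing per resample is the default because
the normalization is defined per dataset; it is also mathematically
inert — min-max scaling of a resample is unchanged by any prior per-marker
affine scaling. Cluster phenotypes are compared with one-way ANOVA
(continuous) and Pearson chi-square (categorical; the published tables do
not name their categorical test, and Pearson is the default convention).
Clustering uses exactly the four markers; MMA and UMFA are summarized post
hoc.

## The synthetic cohort generator

Because the source survey data are not redistributable, the package ships
a generator (`synth_config()`, `generate_cohort()`) that emulates an
NHANES-like cohort of adults 60+ with known ground truth, so every
downstream stage is testable end to end:

* Demographics, comorbidity flags and creatinine are drawn from
  NHANES-like marginals for a 60+ population (age truncated-normal 69 ± 6.7
  on [60, 80]; 50.3% female; published race/marital/education proportions).
* The four markers come from a three-component log-normal mixture — a low,
  an intermediate, and a high folate/B12 cluster with weights 0.65 / 0.30 /
  0.05 and medians (RBC folate, total folate, 5MeTHF, B12) of
  (1000, 42, 39, 403), (2100, 80, 72, 565) and (1900, 190, 165, 2700).
  Biomarkers are positive and right-skewed, hence log-normal. The centers
  follow the published low/intermediate/high cluster pattern, but the
  within-cluster spread (sdlog 0.15) is deliberately tighter than the
  published per-cluster SDs: those SDs describe a fitted partition of
  overlapping survey data, and a mixture simulated from them is not
  identifiable as three groups by any internal validity index (its
  Calinski-Harabasz score is maximal at K = 2 even for the true labels).
  The generator's default is therefore a *well-separated* mixture with the
  right ordering and scale — appropriate for validating recovery machinery,
  not a claim about the real population's separation.
* Each cognitive score is
  `intercept + two-line(driver marker) + covariate effects + N(0, sd)`,
  with one driver marker per test (RBC folate → CERAD-WL, total folate →
  CERAD-DR, 5MeTHF → AF, B12 → DSST), inverted-U slopes (positive below the
  breakpoint, negative above), and default noise SDs equal to about half
  the hinge effect range over the bulk of the marker distribution.
* Low-B12 status is a latent Bernoulli flag (default rate 0.288) realized
  by drawing B12 and MMA from truncated distributions consistent with the
  flag, so the derived rule reproduces the latent truth exactly and a rate
  of 0 yields no flagged records.
* Missingness is injected completely at random (one field per hit record);
  the downstream analysis is complete-case, so MCAR suffices to exercise
  the filter.
* One seeded RNG stream drives the whole cohort; identical `(config,
  seed)` give byte-identical output.

What the generator does *not* emulate: survey weights, strata and PSUs;
within-cluster correlation between markers (independent given the
cluster); integer-valued and range-censored test scores (scores are
continuous Gaussians, so zero-noise checks can be exact); any dependence of
demographics on the biomarker cluster. Passing tests on this generator
therefore validate the estimation machinery under known truth; they do not
certify effect sizes or separation in real survey data.

## Problem sizes and reproducibility

The shipped validation uses desk-scale sizes chosen to exercise the
claimed behavior well inside a normal test run: cohorts of n = 2204 (the
published analysis size) for breakpoint recovery (20 seeds), K selection
(100 seeds at 10 restarts) and stability (B = 200 at 10 restarts per
refit); 2000 replicates at n = 500 for the type-I error of the
non-linearity test; and 50 random instances for the change-point
brute-force equivalence. Field-scale settings (10,000 restarts, B = 2000)
are plain arguments. Every stochastic function takes an explicit seed, and
`run_pipeline()` writes a manifest with the seed, configuration echo,
per-stage row counts and output hashes.

## Known limitations

* The change-point model estimates a single breakpoint; genuinely smooth
  or multi-bend dose-responses are summarized, not represented.
* The Gaussian OLS likelihood underlies all LR tests; heavy-tailed score
  distributions would distort calibration (the bundled calibration check
  is itself Gaussian).
* Min-max normalization is sensitive to single extreme values, which
  compress the bulk of a marker's range; this is inherited from the
  published procedure, not corrected.
* Variance estimates are classical (no survey weights, no sandwich
  correction), matching the published analysis scope.
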