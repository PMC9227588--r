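# folatecog

Nonlinear dose-response analysis between folate/vitamin B12 biomarkers and
cognitive performance in older adults, with unsupervised biomarker
subgrouping.

## The problem

Both deficiency and excess of folate and vitamin B12 have been associated
with worse cognition in people aged 60+, which suggests an **inverted-U
dose-response**: cognitive test scores rise with a biomarker up to some
concentration and decline beyond it. Locating that turning point — and
asking whether biomarker profiles define distinct subgroups of older
adults — requires a specific analysis pipeline that this package
implements end to end for epidemiologists working with participant-level
cohort data (e.g. NHANES-style surveys):

1. **Cohort derivation** — eGFR by the 2009 CKD-EPI creatinine equation;
   low B12 status (B12 < 148 pmol/L or MMA > 210 nmol/L); cognitive
   impairment flags (CERAD-WL < 17 & DR < 5, AF < 14, DSST < 34); dietary
   folate equivalents (DFE = food folate + folic acid/0.6); eligibility
   filtering (age ≥ 60, complete data, eGFR ≥ 60, no stroke) with an
   exclusion audit.
2. **Restricted cubic spline regression** — for each of 4 biomarkers × 4
   cognitive tests, covariate-adjusted OLS with a 3-knot spline (knots at
   the 10th/50th/90th percentiles); non-linearity tested by the likelihood
   ratio `LR = n log(RSS_lin/RSS_spline) ~ χ²(1)`; adjusted
   population-average curves with delta-method 95% bands; B12-status
   subgroup and interaction (2-df LR) analyses.
3. **Change-point estimation** — a continuous two-line model
   `y = b0 + b1·x + b2·(x−c)₊ + covariates`, with the breakpoint `c`
   chosen by exhaustive profile likelihood over all admissible observed
   exposure values.
4. **Subgrouping** — min-max normalization of the four markers, K-means
   (k-means++, multi-restart Lloyd), K selected by the Calinski-Harabasz
   score, cluster reliability by bootstrap Jaccard similarity
   (clusterboot-style), and cluster phenotyping via ANOVA / chi-square
   tables.
5. **Synthetic cohorts** — a generator with a known 3-component biomarker
   mixture, true breakpoints and slopes, and seeded determinism, so every
   stage is testable without access to the original survey.

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(folatecog)

sim  <- generate_cohort(synth_config(n = 2204, seed = 42))
elig <- apply_eligibility(derive_cohort(sim$cohort))
dat  <- elig$cohort
nrow(dat); dplyr::count(elig$log, reason)
#> [1] 1818
#>   reason         n
#> 1 egfr         216
#> 2 incomplete   106
#> 3 stroke        64

rcs_fit(dat, "dsst", "vitamin_b12")
#> Restricted cubic spline model: dsst ~ vitamin_b12 (knots 115.2, 423.3, 619.8)
#> n = 1818, RSS = 7.792e+04, LR non-linearity = 1304.102 (df 1), p = 1.452e-285

fit_changepoint(dat$vitamin_b12, dat$dsst)
#> Two-line change-point fit: breakpoint 599.9 (slopes 0.04577 / -0.01135), n = 1818

norm <- minmax_fit_transform(dat)
select_k(norm$scaled, 2:8, restarts = 20, seed = 42)
#> Calinski-Harabasz K selection: K = 3

sel <- select_k(norm$scaled, 2:8, restarts = 20, seed = 42)
bootstrap_stability(norm$scaled, sel$model, B = 200, seed = 42, restarts = 10)
#>   cluster    n mean_jaccard dissolved
#> 1       1  576        0.995         0
#> 2       2 1177        0.999         0
#> 3       3   65        0.966         0
```

Reading: 386 of 2204 simulated participants are excluded (with one audited
reason each). DSST is strongly non-linear in vitamin B12 (the generator's
true breakpoint is 600 pmol/L with slopes +0.044/−0.012; the fit recovers
599.9 with +0.046/−0.011): DSST rises ~0.046 points per pmol/L up to
~600 pmol/L and declines above. The four normalized markers support
exactly three subgroups (CH maximal at K = 3), all of which are
bootstrap-stable (mean Jaccard > 0.96, no dissolutions).

A single call runs everything and writes per-stage CSVs plus a manifest
(seed, config, row counts, file hashes):

```r
run_pipeline(run_config(synth = synth_config(n = 2204, seed = 1),
                        out_dir = "run1", seed = 1))
```

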