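# bedsurv

Radiotherapy fractionation and head-and-neck cancer survival: mechanistic
biologically effective dose (BED) models with tumour repopulation, a
random-survival-forest exploratory stage with exact Shapley attributions,
and a cross-fitted doubly robust causal stage estimating the effect of
high vs. low BED on restricted mean survival time (RMST) and survival
probability (SP).

The package is aimed at radiation-oncology modellers and biostatisticians
who want to compare fractionation schedules on a biologically meaningful
dose scale and to estimate, rather than merely predict, the survival
consequences of delivering a high biologically effective dose — with a
synthetic cohort generator that makes every stage testable against known
ground truth.

## The models

For *m* fractions of *d* Gy and an α/β ratio *r* (10 Gy for HNSCC):

    BED_simp = m·d·(1 + d/r)

Two repopulation variants subtract dose credit for tumour regrowth over
the elapsed treatment time *T* (days), with background rate *g* and
accelerated repopulation (AR) rate λ:

    BED_DI = [ m·α·d·(d+r)/r − g·T − λ·max(0, T − T_k) ] / α
    BED_DD = [ m·α·d·(d+r)/r − g·T − λ·(1 − e^(−k))·max(0, T − C/k) ] / α,
             k = m·α·d·(d+r) / (r·T)

In the dose-independent (DI) model AR switches on at a fixed time `T_k`;
in the dose-dependent (DD) model AR begins when the cumulative log cell
kill reaches a threshold `C`, so intense daily kill both advances the
onset and raises the rate. The unpublished background rate `g` is
calibrated in closed form from the standard 35 × 2 Gy / 7-week schedule
(`calibrate_repopulation()`).

The causal stage dichotomises a BED variant at a SHAP-guided cut-point
(61.8 Gy for BED_DD by default) and estimates average and per-patient
treatment effects from cross-fitted augmented inverse-propensity-weighted
scores with inverse-probability-of-censoring weighting — doubly robust:
consistent if either the propensity or the outcome model is correct.

## Worked example

Compare hypofractionated schedules against the standard regimen, then
estimate the causal effect of high BED on a synthetic randomized cohort
whose true RMST effect at 8 years is calibrated to 0.5 years:

```r
library(bedsurv)

regs <- data.frame(fractions = c(35, 25, 20, 18),
                   dose_per_fraction = c(2, 2.4, 2.75, 3))
bed_table(regs, r_values = 10)[, c(1:2, 6, 8, 10, 11)]
#> fractions dose_per_fraction bed_simp_10 bed_di_10 bed_dd_10 diff_bed_dd_10
#>        35              2.00       84.00     64.17     62.19           0.00
#>        25              2.40       74.40     65.02     63.28           1.09
#>        20              2.75       70.13     64.14     63.64           1.45
#>        18              3.00       70.20     64.70     63.91           1.72

spec <- solve_bed_loghr(randomized_cohort_spec(n_patients = 5000, seed = 1),
                        target = 0.5, horizon = 8)
d <- sample_cohort(spec)
d$W <- binarize(d$bed_dd, cutpoint_spec("bed_dd"))
est <- estimate_effects(d, causal_task("W", horizons = c(2, 4, 6, 8)),
                        seed = 1, propensity = "glm", outcome = "cox")
est
#> doubly robust effect estimates (n = 5000, glm propensity, cox outcome)
#>  horizon estimand   estimate         se    n
#>        2     RMST 0.03217769 0.01245170 5000
#>        4     RMST 0.11092413 0.03298635 5000
#>        6     RMST 0.22799911 0.05614487 5000
#>        8     RMST 0.38978113 0.08018865 5000
#>        2       SP 2.50496281 1.06720246 5000
#>        4       SP 5.18894866 1.33040701 5000
#>        6       SP 7.11987381 1.43942157 5000
#>        8       SP 7.55846473 1.50096930 5000
```

Hypofractionated schedules lose ground on the naive `BED_simp` scale but
gain 1–2 Gy over the standard regimen once dose-dependent repopulation is
accounted for (`diff_bed_dd_10`). The causal estimates read: patients
above the 61.8 Gy `BED_DD` cut-point gain ≈ 0.39 years of restricted mean
survival (SE 0.08) and ≈ 7.6 percentage points of survival probability
(SE 1.5) by year 8 — within two standard errors of this generator's true
effects (0.50 years, 9.1 points, from the `true_effects()` oracle). A
univariate check agrees: `km_logrank(d, "W")` gives p ≈ 2e-07.

The full pipeline (cohort → BED → forest + SHAP → cut-points → causal →
refutations) runs from one config:

```r
run_pipeline(pipeline_config(cohort = cohort_spec(n_patients = 2000)),
             out_dir = "report")
# or from a shell:
#   Rscript inst/cli/run-pipeline.R --config cfg.yaml --out report --seed 1
```

See `vignettes/bedsurv-methods.Rmd` for the model assumptions, parameter
meanings and all numerical conventions.

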