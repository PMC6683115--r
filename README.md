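# fetalvelo

Latent-class modelling of fetal growth velocity from serial ultrasound
biometry.

## The problem

Routine prenatal care in Japan produces unusually dense ultrasound
series — roughly eleven scans per pregnancy on the standard schedule
(every 4 weeks to week 24, every 2 weeks to week 36, weekly after).
Each scan measures biparietal diameter (BPD), abdominal circumference
(AC) and femur length (FL), combined into an estimated fetal weight by
the JSUM formula

```
EFW[g] = 1.07·BPD³ + 0.3·AC²·FL        (lengths in cm)
```

Fetal *size* is conventionally judged against an averaged growth chart,
but week-over-week growth *velocity* is a different signal: it reflects
how the fetus responds, over time, to the intra-uterine environment.
This package asks whether a cohort's velocity curves hide a small
number of latent trajectory classes, and what distinguishes the fetuses
in each.

It is written for perinatal epidemiologists and biostatisticians
working with longitudinal biometry: the pipeline takes a long-format
visit table plus maternal and neonatal tables, and produces weekly
trajectories, velocities, cohort z-scores, covariate-interaction tests,
a latent-class decomposition with posterior diagnostics, and class-wise
descriptive comparisons.

## The model at the core

Per-subject trajectories: penalized cubic regression splines on
log-measurements (basis dimension `min(n_obs − 1, 10)`, smoothing
parameter by GCV), evaluated at integer weeks 19–38; velocity is the
backward difference `v_w = y_w − y_{w−1}`; weekly sizes and velocities
are standardized against the cohort's own weekly means and SDs.

Latent classes: a finite mixture of linear mixed models for the weekly
velocity z-score series `y_i`,

```
y_i | class g  =  X_i β_g + Z_i b_i + e_i,
b_i ~ N(0, D),   e_i ~ N(0, σ² I),   P(class = g) = π_g,
```

with `X_i` a quartic polynomial basis in centered gestational week and
`Z_i` a subject intercept + slope; `D` and `σ²` shared across classes.
Estimation is by multi-start EM (k-means-seeded, provably monotone
log-likelihood); the number of classes is compared across K = 1..4 by
BIC = −2·logL + p·log(N). Subjects are assigned to their
maximum-posterior class, and the classification is summarized by
per-class mean posteriors and the overall mean maximum posterior.

Covariate screens use `z ~ factor * week + (1 | subject)` by maximum
likelihood with Satterthwaite Wald tests on the interaction
(significance gates: p < 2.7×10⁻⁴ and |slope| > 0.01 z/week). Class
profiles use one-way ANOVA and chi-square tests with Ryan's step-down
pairwise comparison of proportions.

Because cohorts of this kind are not public, the package includes a
synthetic-cohort generator (`sim_config()` / `generate_cohort()`) that
emulates the checkup schedule, three velocity-class archetypes,
week-varying covariate effects, measurement noise and neonatal
outcomes, with ground-truth labels for recovery testing.

## Worked example

```r
library(fetalvelo)

cfg    <- sim_config(n_subjects = 150, seed = 7)
cohort <- generate_cohort(cfg)
funnel <- apply_inclusion_criteria(cohort$visits, cohort$maternal,
                                   cohort$neonatal)
weekly <- cohort_weekly(funnel$visits, parameters = "EFW")
panel  <- build_zscore_panel(weekly$grid)
zgrid  <- apply_zscore_panel(weekly$grid, panel)
vel    <- outcome_long(zgrid, "EFW", "z_velocity")
fit    <- fit_lcmm(vel, lcmm_spec(n_classes = 3), n_starts = 5, seed = 1)
print(fit)
print(posterior_report(fit))
table(assigned = fit$assignment,
      generated = cohort$truth$true_class[match(fit$subject_id,
                                                cohort$truth$subject_id)])
```

Output:

```
Latent-class linear mixed model: K = 3 | N = 150
logLik: -2116.196939  BIC: 4337.61722  iterations: 7 (converged)
class proportions: 0.154 0.714 0.132
sigma2: 0.177453
 class   n proportion mean_posterior
     1  23  0.1533333      0.9983815
     2 107  0.7133333      0.9985397
     3  20  0.1333333      0.9882838
mean max posterior: 0.9971 | relative entropy: 0.9921
        generated
assigned   1   2   3
       1  23   0   0
       2   0 106   1
       3   0   1  19
```

Reading it: the EM converged to a three-class solution whose mixture
weights (15.4% / 71.4% / 13.2%) match the generating proportions; the
mean maximum posterior of 0.997 says subjects are assigned to their
class almost without ambiguity, and the cross-table confirms the
recovered partition differs from the ground truth in only 2 of 150
subjects. Class 1 is the late-deceleration shape, class 2 the steady
majority, class 3 the late-acceleration shape (classes are canonically
ordered by fitted velocity at week 31, so the labels are stable across
runs).

The `analysis/` directory holds the same workflow at study scale
(n = 801) as numbered stage scripts (`01_simulate_cohort.R` …
`06_sensitivity.R`), each writing its tables under `results/`.

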