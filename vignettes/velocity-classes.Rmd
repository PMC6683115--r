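---
title: "Latent classes in fetal growth velocity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent classes in fetal growth velocity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalvelo)
```

## The scientific question

Serial ultrasound biometry gives each fetus a sparse, irregularly timed
set of size measurements: biparietal diameter (BPD), abdominal
circumference (AC) and femur length (FL), combined into an estimated
fetal weight by the JSUM formula

$$\mathrm{EFW}[g] = 1.07\,\mathrm{BPD}^3 + 0.3\,\mathrm{AC}^2\,\mathrm{FL},$$

with all lengths in centimetres. Beyond a fetus's *size*, its
week-over-week growth *velocity* carries information about how it
responds to the intra-uterine environment. This package implements a
pipeline that (i) interpolates each subject's sparse visits to an
integer-week grid, (ii) computes weekly velocities and cohort z-scores,
(iii) tests whether known factors (fetal sex, maternal height,
pre-pregnancy BMI, parity, maternal age) have week-*varying* effects on
size, and (iv) asks whether the cohort hides a small number of latent
velocity-trajectory classes.

Because the kind of clinical cohort this analysis needs is not publicly
available, the package ships a synthetic-cohort generator that emulates
the Japanese prenatal-checkup data structure with known ground truth;
every statistical claim the test-suite makes is a claim about recovery
of that truth.

## Stage 1: eligibility funnel

`apply_inclusion_criteria()` applies, in order: Japanese singleton
pregnancies; maternal age at least 20 years; delivery at or after 28.0
weeks; at least one scan before 22 weeks; longest interval between
consecutive scans strictly under 5 weeks; one delivery per woman (the
lowest delivery index is kept — the rule is boundary-ambiguous in
general descriptions of such funnels, so the earliest delivery was
chosen and is config-overridable); and, when the last scan falls within
one week of delivery, agreement between the last EFW and the actual
birthweight within 20%. Age and delivery-week rules are read
boundary-inclusive. Every step's remaining count is reported, so the
funnel doubles as a data-quality report.

## Stage 2: weekly trajectories, velocities, z-scores

Each subject's log-transformed measurements of each parameter are
smoothed by a penalized cubic regression spline
(`mgcv::gam`), basis dimension $\min(n_{\mathrm{obs}}-1,\,10)$, with the
smoothing parameter chosen by generalized cross-validation. GCV was
preferred over REML because it is a deterministic, distribution-free
choice for an interpolation task; the criterion is switchable. The
basis uses cubic B-splines: the basis must contain *all* cubic
polynomials so that noiseless polynomial trajectories are recovered
exactly (natural-spline bases impose zero second derivatives at the
boundary and leave a small but systematic bias); for subjects with
fewer than six visits a natural-spline basis is the fallback.

Weekly values are the exponentiated fits at integer weeks 19–38, the
window in which interpolated estimates are stable. A fit is never
extrapolated more than 3 weeks past the subject's last scan; later grid
weeks are flagged missing rather than guessed. Velocity is the backward
difference $v_w = y_w - y_{w-1}$ on the natural scale, indexed by the
later week, so a 19–38 value grid yields velocities on 20–38. The
telescoping identity $\sum_w v_w = y_{38} - y_{19}$ holds to floating
precision and is asserted in the tests.

Weekly sizes *and* velocities are standardized against the cohort's own
weekly means and SDs (sample SD, $n-1$): velocities get their own
weekly reference rather than reusing the size SDs, since the two
quantities have entirely different scales and variance profiles. A
panel built on one cohort can be re-applied to new subjects.

## Stage 3: week-varying covariate effects

For each factor and each outcome parameter the model is the linear
mixed model

$$z_{ij} = \beta_0 + \beta_f f_i + \beta_t t_j + \beta_{ft} f_i t_j
  + b_i + \varepsilon_{ij}, \qquad b_i \sim N(0, \tau^2),$$

fitted by maximum likelihood with time centered at week 19, so the
factor main effect is the week-19 contrast. The factor-by-week
coefficient $\beta_{ft}$ (z-units per week) is tested with a Wald test
using Satterthwaite denominator degrees of freedom (lmerTest);
Kenward–Roger is available as an option. A level is flagged when
$p < 2.7\times 10^{-4}$ — the Bonferroni-style threshold used in this
literature, kept as a configurable constant because the implied test
count cannot be derived exactly — and $|\beta_{ft}| > 0.01$ z/week, the
only scale on which an effect-size gate of 0.01 is dimensionally
sensible here. The number of tests actually performed is recorded on
the results table.

## Stage 4: the latent-class linear mixed model

The core of the package is a from-scratch latent-class linear mixed
model for a weekly outcome series $y_i$ (EFW velocity z-scores by
default). Conditional on latent class $g$,

$$y_i = X_i\beta_g + Z_i b_i + e_i, \qquad
  b_i \sim N(0, D), \quad e_i \sim N(0, \sigma^2 I),$$

where $X_i$ is an orthogonalized polynomial basis of degree 4 in
gestational week centered at 28.5 (the midpoint of the analysis
window; orthogonalization is purely for numerical conditioning and a
raw-coefficient back-transformation is provided), and $Z_i$ is subject
intercept plus centered week. $D$ and $\sigma^2$ are shared across
classes; class membership has intercept-only multinomial weights
$\pi_g$. The random structure includes the intercept because that is
the conventional reading of an R-style `random = ~time` term;
a slope-only option is exposed.

The marginal likelihood
$\sum_i \log \sum_g \pi_g\, N(y_i;\, X_i\beta_g,\, Z_i D Z_i' +
\sigma^2 I)$ is evaluated via one Cholesky factorization per
observation pattern (subjects sharing a missing-week pattern share
$V_i$), with the class sum in log space.

**Estimation.** Each EM iteration runs two generalized-EM cycles:

1. E-step over class membership only (random effects integrated
   analytically), then an exact weighted-GLS update of each $\beta_g$ —
   the maximizer of the expected complete-data log-likelihood in
   $\beta$.
2. E-step over (class, random effects), then closed-form updates of
   $\pi$, $D$ (from $E[b_ib_i' \mid y_i, g]$) and $\sigma^2$ (from the
   conditional residual moments).

Both cycles maximize the relevant minorant, so the observed-data
log-likelihood is non-decreasing at every iteration — asserted to
$10^{-10}$ relative tolerance in the tests, not just "approximately
monotone". EM was chosen over quasi-Newton precisely because it turns
monotonicity into a checkable invariant. Convergence is declared at a
relative log-likelihood change below $10^{-8}$ (at most 500
iterations). Starts (default 20) are seeded from k-means on per-subject
least-squares polynomial coefficients, with random relabelling
perturbations thereafter; the best converged start wins. Degenerate
collapses (an emptying class, $\sigma^2 \to 0$) abort a start rather
than being papered over.

**Canonical ordering.** Mixture labels are arbitrary, so classes are
reordered by descending fitted mean outcome at week 31 — the week at
which the late-decelerating and steady shapes separate most cleanly —
giving stable labels: class 1 = late deceleration, class 2 = steady
majority, class 3 = late acceleration.

**Model selection.** `select_k()` fits each $K$ with shared settings
and compares $\mathrm{BIC} = -2\log L + p\log N$ with $N$ the number of
subjects. `posterior_report()` summarizes the classification: per-class
mean posterior among assigned members, the overall mean of each
subject's maximum posterior, and a relative-entropy quality score.

**Outcome scale.** The mixture is fitted on weekly velocity
*z-scores*. On the natural scale (grams/week) a subject's overall size
multiplies its entire velocity curve, so the mixture stratifies on size
rather than shape; per-week standardization absorbs that multiplicative
factor into the random intercept and leaves the *shape* signal to the
classes. This was verified directly in development: natural-scale and
mean-relative outcomes recover the generating classes far worse than
z-scores under identical settings.

**What BIC does on pipeline data.** On cohorts generated by the full
trajectory-plus-interpolation pipeline, the within-subject deviations
from a class mean are *smooth* (spline interpolation between sparse
early visits leaves strongly autocorrelated residuals), while the model
assumes intercept + slope + white noise. A shared-variance Gaussian
mixture can therefore keep buying log-likelihood with additional
classes that cluster those smooth residual curves, and the BIC curve
can continue to fall past the generating number of classes even when
the three-class fit recovers the true partition almost perfectly (the
tests compute adjusted Rand indices above 0.9 and mean maximum
posteriors above 0.99 at study scale). The acceptance suite states the
class-count check exactly as specified and reports its honest outcome;
all downstream profiling uses the three-class model, which is the
selected structure in this analysis design.

## Stage 5: class profiles

Continuous characteristics are compared across classes by one-way
ANOVA; categorical ones by the chi-square test, followed — for binary
traits — by Ryan's step-down multiple comparison of proportions: classes
ordered by proportion, a pair of ordered rank-span $r$ tested at
$\alpha' = 2\alpha / (k(r-1))$, and a narrower pair examined only when
every pair spanning it was significant, which makes the scheme coherent
by construction. Pairwise tests use the chi-square form without
continuity correction, the same family as the omnibus statistic. Ryan's
1960 formula is used; the variant is a documented constant of the
implementation. Body-proportion (AC/FL, AC/BPD) mean curves per class,
an examiner-homogeneity chi-square (restricted to examiners with at
least 100 subjects, attribution by most-visits-ties-to-earliest), and
sensitivity refits excluding flagged subgroups complete the stage.

## The synthetic cohort generator

`sim_config()` defaults define the study conditions:

* **n = 801**, class proportions $118/592/91$.
* **Class archetypes** are quartic polynomials in centered week for
  log-EFW velocity. The steady class is a least-squares quartic fit to
  the log-derivative of a spline through anchor EFW medians typical of
  Japanese growth charts; the minority classes add deviations fitted as
  cubics to target offsets (an acceleration hump over 25–32 weeks with
  a marked late deceleration; a dip near 25 with re-acceleration from
  32). Outside the 19–39 week window the archetype velocity continues
  by its first-order Taylor extension, keeping early scans and
  post-term deliveries on a tame, twice-differentiable curve. The
  deviation magnitudes were calibrated once, in development, so that
  the noiseless class curves satisfy the qualitative orderings
  described for the study's figures *and* the classes are as cleanly
  separated as the study's reported posteriors (>92%) imply; they were
  then frozen.
* **Subject-level variation**: a baseline log-size intercept
  (SD 0.05), random intercept (SD 0.005/week) and slope
  (SD 0.0005/week²) on the log-velocity scale. An optional week-level
  white-noise roughness (`resid_sd`, default 0) makes true trajectories
  non-smooth.
* **Visit process**: first visit uniform on weeks 11–15, then the
  checkup schedule (every 4 weeks to 24, every 2 to 36, weekly to
  delivery), ±0.3-week jitter; class-specific delivery distributions
  (means 39.5/39.3/38.4, truncated to 33–41.5 weeks).
* **Measurement noise**: multiplicative log-normal per parameter
  (CV 1.0% BPD, 1.5% AC, 1.2% FL — intra-observer repeatability of
  trained examiners); the recorded EFW is recomputed from the *noisy*
  biometry, as ultrasound equipment does. Consistency is preserved the
  other way too: AC is back-solved from the true EFW, BPD and FL
  curves, so the EFW formula applied to noiseless biometry reproduces
  the true trajectory exactly and the class signal is carried mainly by
  AC.
* **Covariate effects** in z-units with per-week slopes: males larger
  in BPD/AC/EFW at week 19 with the gap shrinking late; BMI groups
  diverging in AC/EFW over time from no week-19 gap; height acting on
  FL and increasingly on BPD; a small late parity gain; no age effect.
* **Reproducibility**: one global seed drives per-subject substreams,
  so any subject's data is invariant to cohort size and ordering.

What the generator does *not* emulate: the joint distribution of
maternal covariates beyond marginal ranges, gestational-age dating
error, true biological autocorrelation structure of growth, or
real-world missingness patterns. Passing recovery tests on this
generator therefore shows the estimator is correct and well-calibrated
under the stated data structure — not that every finding would
replicate on clinical data.

## Numerical choices and degenerate inputs

* Spline fits need at least 4 visits; fewer yields a logged exclusion,
  not an error. A z-score cell with fewer than 2 subjects or zero SD is
  a hard error naming the cell.
* The mixture needs at least 3 observed weeks per subject and more
  distinct weeks than the polynomial degree.
* $\pi$ components are floored at $10^{-12}$ during EM for log-space
  safety; $\sigma^2$ at $10^{-12}$ (hitting it marks the start failed).
* The funnel's boundary conventions (age ≥ 20, delivery ≥ 28.0, gap
  < 5.0 strict, 20% rule only within one week of delivery) are
  explicit `funnel_config()` parameters.
* Problem sizes in the test-suite were chosen to exercise the study
  scale where the claim demands it (one n = 801 cohort with 20 EM
  starts per K; 50 recovery replicates at n = 400 with 4 starts, where
  the k-means initialization makes extra starts redundant; 200 null
  replicates for test calibration) and small fixtures (n = 12, n = 120)
  everywhere else.

## Known limitations

* Variance components are shared across classes; a class-specific
  option is a natural extension but is deliberately off, matching the
  default of the field's standard implementation.
* No covariates enter the class-membership or trajectory submodels, by
  design.
* BIC-based class-count selection inherits the misspecification
  sensitivity discussed above; on real cohorts the BIC table should be
  read alongside the posterior quality report, not alone.
* The examiner model attributes each subject to one primary examiner;
  visit-level examiner effects are not modelled.
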