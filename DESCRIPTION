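Package: fetalvelo
Title: Latent-Class Modelling of Fetal Growth Velocity from Serial
    Ultrasound Biometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study heterogeneity in fetal growth velocity from
    serial ultrasound biometry. Interpolates sparse visit-level biometry
    (biparietal diameter, abdominal circumference, femur length and the
    derived estimated fetal weight) to an integer-week grid with
    smoothing splines, computes week-over-week growth velocities and
    cohort z-scores, tests week-varying covariate effects with linear
    mixed models, and discovers latent velocity-trajectory classes with
    a latent-class linear mixed model estimated by an EM algorithm with
    BIC-based selection of the number of classes. Includes a synthetic
    cohort generator that emulates the Japanese prenatal checkup
    schedule with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    withr
Config/testthat/edition: 3
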