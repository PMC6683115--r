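#' Default latent-class velocity archetypes
#'
#' The three class archetypes are quartic polynomials in centered
#' gestational week for log-EFW velocity (log grams per week). The steady
#' majority class (class 2) is a least-squares quartic fit to the
#' derivative of a natural-spline interpolant through anchor EFW medians
#' typical of Japanese fetal growth. The minority classes are the same
#' base curve plus quartic deviations fitted to target offsets: class 1
#' adds an acceleration hump over weeks 25--32 followed by a marked
#' late-gestation deceleration; class 3 dips around week 25 and
#' re-accelerates from week 32 onwards.
#'
#' @param center centering week (default 28.5).
#' @return 3 x 5 matrix; row g holds coefficients of
#'   `(week - center)^0 .. ^4` for class g's log-velocity.
#' @export
default_archetypes <- function(center = 28.5) {
  anchor_week <- c(11, 13, 15, 17, 19, 22, 25, 28, 31, 34, 36, 38, 40)
  anchor_efw <- c(8, 30, 70, 140, 240, 470, 800, 1200, 1700, 2250,
                  2600, 2900, 3150)
  sp <- stats::splinefun(anchor_week, log(anchor_efw), method = "natural")
  tg <- seq(19, 38, by = 0.5)
  base <- qr.solve(outer(tg - center, 0:4, "^"), sp(tg, deriv = 1))
  dev_week <- c(19, 21, 23, 25, 27, 29, 31, 33, 35, 37, 38)
  d1 <- 2.7 * c(0, 0.001, 0.003, 0.006, 0.013, 0.016, 0.012, 0.002,
                -0.008, -0.016, -0.020)
  d3 <- 2.7 * c(0.002, -0.002, -0.007, -0.010, -0.007, -0.002, 0.002, 0.007,
                0.012, 0.016, 0.018)
  # deviations are fitted as cubics (their shapes need no quartic term and
  # lower degree keeps the polynomial tails tame near the window edges)
  Vd <- outer(dev_week - center, 0:3, "^")
  pad <- function(b) c(b, 0)
  out <- rbind(base + pad(qr.solve(Vd, d1)), base,
               base + pad(qr.solve(Vd, d3)))
  dimnames(out) <- list(paste0("class", 1:3), paste0("u", 0:4))
  out
}

#' Default week-varying covariate effects on fetal size
#'
#' Effects are expressed in cohort z-units as `c(base, slope)` pairs: the
#' adjustment to a parameter's log-scale value at week `w` is
#' `(base + slope * (w - 19)) * z_unit_log[parameter]`. Defaults emulate
#' the reported patterns: males larger in BPD/AC/EFW at 19 weeks with the
#' gap shrinking late in gestation and no sex effect on FL; maternal
#' height acting on FL and increasingly on BPD; pre-pregnancy BMI groups
#' diverging in AC/EFW over time with no week-19 gap; parity adding a
#' small late gain; no maternal-age effect.
#'
#' @return nested list: factor -> parameter -> c(base, slope).
#' @export
default_covariate_effects <- function() {
  list(
    sex_male = list(EFW = c(0.35, -0.012), BPD = c(0.30, -0.008),
                    FL = c(0, 0)),
    bmi_lean = list(EFW = c(0, -0.012)),
    bmi_overweight = list(EFW = c(0, 0.015)),
    height_z = list(FL = c(0.12, 0.003), BPD = c(0, 0.006)),
    parity_multiparous = list(EFW = c(0, 0.008)))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 801 subjects; latent class
#' proportions 118/592/91; the Japanese prenatal checkup schedule (every 4
#' weeks to 24, every 2 weeks to 36, weekly after); class-specific
#' delivery-week distributions; multiplicative measurement noise on each
#' biometry parameter; and subject-level variation as a baseline log-size
#' intercept plus random intercept/slope on the log-velocity scale.
#'
#' @param n_subjects cohort size.
#' @param seed global seed; every subject draws from a deterministic
#'   substream of it, so subject-level output is invariant to cohort
#'   ordering.
#' @param class_proportions simplex of latent class weights.
#' @param class_archetypes matrix of quartic log-velocity coefficients per
#'   class (rows), see [default_archetypes()].
#' @param center centering week of the archetype polynomials.
#' @param log_efw_19 population baseline log EFW at week 19.
#' @param size_sd SD of the subject baseline log-size intercept.
#' @param random_intercept_sd,random_slope_sd SDs of the subject random
#'   intercept/slope on the log-velocity scale (per week, per week^2).
#' @param resid_sd SD of independent week-level log-velocity roughness
#'   (0 keeps true trajectories exactly smooth).
#' @param noise_cv multiplicative measurement coefficient of variation per
#'   biometry parameter (named: bpd, ac, fl); EFW noise is induced by
#'   recomputing the formula from noisy biometry, as the ultrasound
#'   equipment does.
#' @param z_unit_log log-scale SD equivalents of one z-unit per parameter,
#'   used to apply `covariate_effects`.
#' @param covariate_effects see [default_covariate_effects()].
#' @param first_visit_weeks integer support of the first-visit week.
#' @param schedule_breaks,schedule_steps visit intervals: step
#'   `schedule_steps[j]` applies while the current week is below
#'   `schedule_breaks[j]`.
#' @param visit_jitter half-width of the uniform jitter on visit weeks.
#' @param delivery_mean,delivery_sd,delivery_range per-class truncated
#'   normal for gestational age at delivery.
#' @param birthweight_noise_sd log-scale SD of birthweight around the true
#'   trajectory at delivery.
#' @param pct_ref_sd log-scale SD of the reference distribution used to
#'   convert birthweight to a percentile for gestational age.
#' @param examiner_probs examiner workload distribution; a subject's
#'   visits are performed by their primary examiner with probability
#'   `examiner_primary_p`, otherwise by a random colleague.
#' @param examiner_primary_p see above.
#' @param hfd_cut,lfd_cut percentile cut-offs for heavy- and
#'   light-for-date.
#' @return list of class `fv_sim_config`.
#' @export
sim_config <- function(n_subjects = 801, seed = 1,
                       class_proportions = c(118, 592, 91) / 801,
                       class_archetypes = default_archetypes(),
                       center = 28.5,
                       log_efw_19 = log(240),
                       size_sd = 0.05,
                       random_intercept_sd = 0.005,
                       random_slope_sd = 0.0005,
                       resid_sd = 0,
                       noise_cv = c(bpd = 0.010, ac = 0.015, fl = 0.012),
                       z_unit_log = c(EFW = 0.10, BPD = 0.03, FL = 0.035),
                       covariate_effects = default_covariate_effects(),
                       first_visit_weeks = 11:15,
                       schedule_breaks = c(24, 36, Inf),
                       schedule_steps = c(4, 2, 1),
                       visit_jitter = 0.3,
                       delivery_mean = c(39.5, 39.3, 38.4),
                       delivery_sd = c(1.2, 1.5, 1.3),
                       delivery_range = c(33, 41.5),
                       birthweight_noise_sd = 0.025,
                       pct_ref_sd = 0.11,
                       examiner_probs = c(D1 = 0.28, D2 = 0.25, D3 = 0.22,
                                          D4 = 0.15, D5 = 0.10),
                       examiner_primary_p = 0.75,
                       hfd_cut = 90, lfd_cut = 10) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  class_proportions <- as.numeric(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-12)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (any(class_proportions < 0))
    stop("class_proportions must be non-negative", call. = FALSE)
  stopifnot(nrow(class_archetypes) == length(class_proportions),
            size_sd >= 0, random_intercept_sd >= 0, random_slope_sd >= 0,
            resid_sd >= 0, all(schedule_steps > 0))
  if (delivery_range[1] <= max(first_visit_weeks))
    stop("delivery window starts before the visit schedule", call. = FALSE)
  structure(as.list(environment()), class = "fv_sim_config")
}

# ---- deterministic per-subject substreams -------------------------------

.subject_seed <- function(seed, i) (seed + 7919 * i) %% 2147483629L

#' Draw latent class labels
#'
#' Reproducible given the global seed; subject i's label depends only on
#' the seed and i, not on the other subjects.
#'
#' @param n number of subjects.
#' @param proportions class proportions on the simplex.
#' @param seed global seed.
#' @return integer labels in `1:length(proportions)`.
#' @export
sample_class_labels <- function(n, proportions, seed) {
  proportions <- as.numeric(proportions)
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1", call. = FALSE)
  cuts <- cumsum(proportions)[-length(proportions)]
  vapply(seq_len(n), function(i) {
    set.seed(.subject_seed(seed, i))
    findInterval(stats::runif(1), cuts) + 1L
  }, 1L)
}

# ---- true curves --------------------------------------------------------

# Reference BPD / FL median curves (cm): quadratics through anchor points.
.ref_quadratic <- function(weeks, values) {
  co <- solve(outer(weeks, 0:2, "^"), values)
  function(t) co[1] + co[2] * t + co[3] * t^2
}
.bpd_ref <- .ref_quadratic(c(12, 28, 40), c(2.0, 7.2, 9.3))
.fl_ref <- .ref_quadratic(c(12, 28, 40), c(0.8, 5.2, 7.2))

# Antiderivative of a polynomial (coefficients of u^0..u^d) at u.
.poly_int <- function(coef, u) {
  j <- seq_along(coef)
  sapply(u, function(x) sum(coef * x^j / j))
}

# Evaluate an expression under a temporary RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Cumulative week-level roughness of the true log-size trajectory.
# resid_sd adds an independent N(0, resid_sd) increment to the log-EFW
# weekly velocity at each integer week (growth is not perfectly smooth);
# the cumulative process is anchored at 0 at week 19 and linearly
# interpolated between integer weeks. Regenerated deterministically from
# the subject's rough_seed so the truth table stays flat.
.rough_weeks <- 9:43
.roughness_cum <- function(t, truth_row, config) {
  if (config$resid_sd == 0 || is.null(truth_row$rough_seed) ||
      is.na(truth_row$rough_seed))
    return(numeric(length(t)))
  delta <- .with_seed(truth_row$rough_seed,
                      stats::rnorm(length(.rough_weeks), 0, config$resid_sd))
  # delta[k] is the velocity roughness of the week ending at .rough_weeks[k]
  cum <- cumsum(delta)
  cum <- cum - cum[match(19, .rough_weeks)]
  stats::approx(.rough_weeks, cum, xout = t, rule = 2)$y
}

#' True log-EFW trajectory of a synthetic subject
#'
#' Integrates the subject's class archetype plus random intercept/slope on
#' the log-velocity scale from week 19, anchored at the baseline log size,
#' and adds the week-varying covariate effect. The archetype polynomial
#' applies on the 19--39 week analysis window; outside it the class
#' log-velocity is held at its boundary value, so early scans and
#' post-term deliveries see a smooth, tame extension rather than the
#' polynomial's tails.
#'
#' @param t gestational weeks (vector).
#' @param truth_row one row of the cohort truth table.
#' @param config the generating `fv_sim_config`.
#' @return log EFW (log grams) at `t`.
#' @export
true_log_efw <- function(t, truth_row, config) {
  u <- pmin(pmax(t, 19), 39) - config$center
  u19 <- 19 - config$center
  u39 <- 39 - config$center
  arch <- config$class_archetypes[truth_row$true_class, ]
  deg <- length(arch) - 1L
  pows <- function(x) drop(outer(x, 0:deg, "^") %*% arch)
  dpows <- function(x) drop(outer(x, 0:(deg - 1), "^") %*%
                              (arch[-1] * seq_len(deg)))
  lo <- pmin(t - 19, 0); hi <- pmax(t - 39, 0)
  integral <- .poly_int(arch, u) - .poly_int(arch, u19) +
    lo * pows(u19) + lo^2 / 2 * dpows(u19) +
    hi * pows(u39) + hi^2 / 2 * dpows(u39)
  uu <- t - config$center
  integral <- integral +
    truth_row$b0 * (uu - u19) + truth_row$b1 * (uu^2 - u19^2) / 2
  config$log_efw_19 + truth_row$size_intercept + integral +
    config$z_unit_log[["EFW"]] *
      (truth_row$eff_base_EFW + truth_row$eff_slope_EFW * (t - 19)) +
    .roughness_cum(t, truth_row, config)
}

#' True log-velocity of a synthetic subject
#'
#' The smooth component of d/dt log EFW (week-level roughness, when
#' enabled via `resid_sd`, enters the sizes through [true_log_efw()]).
#'
#' @inheritParams true_log_efw
#' @return d/dt log EFW at `t` (per week).
#' @export
true_log_velocity <- function(t, truth_row, config) {
  tc <- pmin(pmax(t, 19), 39)
  u <- tc - config$center
  arch <- config$class_archetypes[truth_row$true_class, ]
  deg <- length(arch) - 1L
  v <- drop(outer(u, 0:deg, "^") %*% arch) +
    # first-order extension outside the 19-39 week window
    (t - tc) * drop(outer(u, 0:(deg - 1), "^") %*%
                      (arch[-1] * seq_len(deg)))
  v + truth_row$b0 + truth_row$b1 * (t - config$center) +
    config$z_unit_log[["EFW"]] * truth_row$eff_slope_EFW
}

# True BPD / FL / AC (cm) at weeks t; AC is back-solved so that the EFW
# formula applied to noiseless biometry reproduces the true EFW exactly.
.true_biometry <- function(t, truth_row, config) {
  efw <- exp(true_log_efw(t, truth_row, config))
  bpd <- .bpd_ref(t) * exp(truth_row$s_bpd + config$z_unit_log[["BPD"]] *
    (truth_row$eff_base_BPD + truth_row$eff_slope_BPD * (t - 19)))
  fl <- .fl_ref(t) * exp(truth_row$s_fl + config$z_unit_log[["FL"]] *
    (truth_row$eff_base_FL + truth_row$eff_slope_FL * (t - 19)))
  # keep the head term strictly below EFW so AC^2 stays positive
  cap <- (efw / (1.3 * 1.07))^(1 / 3)
  bpd <- pmin(bpd, cap)
  ac <- sqrt((efw - 1.07 * bpd^3) / (0.3 * fl))
  data.frame(t = t, efw = efw, bpd = bpd, ac = ac, fl = fl)
}

# Sum the covariate effects for one subject into per-parameter
# (base, slope) totals in z-units.
.subject_effects <- function(cov, config) {
  eff <- list(EFW = c(0, 0), BPD = c(0, 0), FL = c(0, 0))
  add <- function(eff, factor_name, scale = 1) {
    fx <- config$covariate_effects[[factor_name]]
    for (p in names(fx)) eff[[p]] <- eff[[p]] + scale * fx[[p]]
    eff
  }
  if (isTRUE(cov$sex_male)) eff <- add(eff, "sex_male")
  if (cov$prepreg_bmi < 18.5) eff <- add(eff, "bmi_lean")
  if (cov$prepreg_bmi > 25) eff <- add(eff, "bmi_overweight")
  eff <- add(eff, "height_z", scale = (cov$height_cm - 159.1) / 5.3)
  if (isTRUE(cov$parity_multiparous)) eff <- add(eff, "parity_multiparous")
  eff
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

.planned_visits <- function(first, delivery, config) {
  w <- first; out <- first
  repeat {
    step <- config$schedule_steps[findInterval(w, config$schedule_breaks) + 1L]
    w <- w + step
    if (w > delivery) break
    out <- c(out, w)
  }
  out
}

#' Simulate one subject's visits and outcomes
#'
#' Draws the subject's latent quantities (random effects, delivery week,
#' visit schedule with jitter), evaluates the true biometry at each visit,
#' applies multiplicative log-normal measurement noise, and derives the
#' neonatal record from the true trajectory at delivery.
#'
#' @param class_label latent class (row of `config$class_archetypes`).
#' @param covariates list/row with `sex_male`, `height_cm`, `prepreg_bmi`,
#'   `prepreg_weight_kg`, `parity_multiparous`.
#' @param config an `fv_sim_config`.
#' @param seed substream seed for this subject.
#' @return list with `truth` (1-row data.frame of latent quantities),
#'   `visits`, `neonatal`.
#' @export
simulate_subject <- function(class_label, covariates, config, seed) {
  if (class_label > nrow(config$class_archetypes))
    stop("no archetype defined for class ", class_label, call. = FALSE)
  set.seed(seed)
  eff <- .subject_effects(covariates, config)
  truth <- data.frame(
    true_class = class_label,
    size_intercept = stats::rnorm(1, 0, config$size_sd),
    b0 = stats::rnorm(1, 0, config$random_intercept_sd),
    b1 = stats::rnorm(1, 0, config$random_slope_sd),
    s_bpd = stats::rnorm(1, 0, 0.018),
    s_fl = stats::rnorm(1, 0, 0.018),
    eff_base_EFW = eff$EFW[1], eff_slope_EFW = eff$EFW[2],
    eff_base_BPD = eff$BPD[1], eff_slope_BPD = eff$BPD[2],
    eff_base_FL = eff$FL[1], eff_slope_FL = eff$FL[2],
    rough_seed = (seed + 104729) %% 2147483629)
  truth$s_bpd <- truth$s_bpd + 0.25 * truth$size_intercept
  truth$s_fl <- truth$s_fl + 0.20 * truth$size_intercept

  delivery <- .rtruncnorm1(config$delivery_mean[class_label],
                           config$delivery_sd[class_label],
                           config$delivery_range[1], config$delivery_range[2])
  first <- config$first_visit_weeks[
    sample.int(length(config$first_visit_weeks), 1L)]
  if (delivery <= first)
    stop("delivery before the first scheduled visit", call. = FALSE)
  planned <- .planned_visits(first, delivery, config)
  ga <- sort(planned + stats::runif(length(planned), -config$visit_jitter,
                                    config$visit_jitter))
  ga <- pmin(ga, delivery - 0.05)
  ga <- ga[!duplicated(round(ga, 3))]
  truth$delivery_ga <- delivery
  truth$first_visit <- first

  bio <- .true_biometry(ga, truth, config)
  nv <- length(ga)
  bpd_obs <- bio$bpd * exp(stats::rnorm(nv, 0, config$noise_cv[["bpd"]]))
  ac_obs <- bio$ac * exp(stats::rnorm(nv, 0, config$noise_cv[["ac"]]))
  fl_obs <- bio$fl * exp(stats::rnorm(nv, 0, config$noise_cv[["fl"]]))

  # maternal weight: gain from ~week 13, modulated by BMI group and class
  bmi_adj <- if (covariates$prepreg_bmi < 18.5) 1.1 else
    if (covariates$prepreg_bmi > 25) 0.8 else 1
  class_adj <- c(1.08, 1, 1)[class_label]
  gain <- pmax(0, ga - 13) * 0.38 * bmi_adj * class_adj +
    stats::rnorm(nv, 0, 0.3)
  mweight <- covariates$prepreg_weight_kg + gain

  primary <- sample(names(config$examiner_probs), 1L,
                    prob = config$examiner_probs)
  others <- setdiff(names(config$examiner_probs), primary)
  use_primary <- stats::runif(nv) < config$examiner_primary_p
  examiner <- ifelse(use_primary, primary,
                     sample(others, nv, replace = TRUE))
  truth$primary_examiner <- primary

  visits <- data.frame(
    ga_weeks = ga, bpd_cm = bpd_obs, ac_cm = ac_obs, fl_cm = fl_obs,
    efw_g = compute_efw(bpd_obs, ac_obs, fl_obs),
    examiner_id = examiner, maternal_weight_kg = mweight)

  # neonatal outcomes from the true trajectory at delivery
  log_bw <- true_log_efw(delivery, truth, config) +
    stats::rnorm(1, 0, config$birthweight_noise_sd)
  bw <- exp(log_bw)
  ref_row <- data.frame(true_class = min(2L, nrow(config$class_archetypes)),
                        size_intercept = 0, b0 = 0, b1 = 0,
                        eff_base_EFW = 0, eff_slope_EFW = 0)
  mu_ref <- true_log_efw(delivery, ref_row, config)
  z_w <- (log_bw - mu_ref) / config$pct_ref_sd
  z_len <- 0.6 * z_w + sqrt(1 - 0.36) * stats::rnorm(1)
  z_head <- 0.5 * z_w + sqrt(1 - 0.25) * stats::rnorm(1)
  z_chest <- 0.7 * z_w + sqrt(1 - 0.49) * stats::rnorm(1)
  weight_pct <- 100 * stats::pnorm(z_w)
  length_pct <- 100 * stats::pnorm(z_len)
  head_pct <- 100 * stats::pnorm(z_head)
  size_category <- if (weight_pct >= config$hfd_cut) "HFD" else
    if (weight_pct <= config$lfd_cut && length_pct <= config$lfd_cut) "SGA" else
    if (weight_pct <= config$lfd_cut) "LFD" else "AGA"
  neonatal <- data.frame(
    sex_male = covariates$sex_male,
    ga_delivery_weeks = delivery,
    birthweight_g = bw,
    length_cm = 49.4 + 1.8 * z_len + 0.9 * (delivery - 39.2),
    head_circ_cm = 33.4 + 1.2 * z_head + 0.4 * (delivery - 39.2),
    chest_circ_cm = 31.8 + 1.5 * z_chest + 0.6 * (delivery - 39.2),
    weight_pct = weight_pct, length_pct = length_pct, head_pct = head_pct,
    size_category = size_category,
    placenta_g = bw / exp(stats::rnorm(1, log(5.5), 0.16)))
  list(truth = truth, visits = visits, neonatal = neonatal)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces the three interchange tables (visits, maternal, neonatal) plus
#' a truth table with each subject's latent class and generating
#' quantities. Fully reproducible from `config$seed`; each subject draws
#' from its own substream, so results are invariant to cohort ordering.
#'
#' @param config an [sim_config()].
#' @return list of class `fv_cohort` with `visits`, `maternal`,
#'   `neonatal`, `truth`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "fv_sim_config"))
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  labels <- sample_class_labels(n, config$class_proportions, config$seed)
  visits <- list(); maternal <- list(); neonatal <- list(); truth <- list()
  for (i in seq_len(n)) {
    ss <- .subject_seed(config$seed, i)
    set.seed(ss)
    stats::runif(1)  # consumed by the class-label draw
    cov <- list(
      sex_male = stats::runif(1) < 0.537,
      age_years = .rtruncnorm1(33.7, 4.6, 20, 45),
      height_cm = stats::rnorm(1, 159.1, 5.3),
      prepreg_bmi = exp(stats::rnorm(1, log(20.7), 0.14)),
      parity_multiparous = stats::runif(1) < 0.336,
      poor_obstetric_history = stats::runif(1) < 0.021,
      complications = stats::runif(1) < 0.030,
      disease_history = stats::runif(1) < 0.248,
      assisted_conception = stats::runif(1) < 0.162,
      smoking_pre = stats::runif(1) < 0.066,
      smoking_during = stats::runif(1) < 0.006)
    cov$prepreg_weight_kg <- cov$prepreg_bmi * (cov$height_cm / 100)^2
    sim <- simulate_subject(labels[i], cov, config, seed = ss + 1L)
    sim$visits$subject_id <- ids[i]
    sim$neonatal$subject_id <- ids[i]
    sim$truth$subject_id <- ids[i]
    maternal[[i]] <- data.frame(
      subject_id = ids[i], woman_id = ids[i], delivery_index = 1L,
      age_years = cov$age_years, height_cm = cov$height_cm,
      prepreg_weight_kg = cov$prepreg_weight_kg,
      prepreg_bmi = cov$prepreg_bmi,
      parity_multiparous = cov$parity_multiparous,
      poor_obstetric_history = cov$poor_obstetric_history,
      complications = cov$complications,
      disease_history = cov$disease_history,
      assisted_conception = cov$assisted_conception,
      smoking_pre = cov$smoking_pre,
      smoking_during = cov$smoking_during,
      ethnicity_japanese = TRUE, singleton = TRUE)
    visits[[i]] <- sim$visits
    neonatal[[i]] <- sim$neonatal
    truth[[i]] <- sim$truth
  }
  first_cols <- function(d) d[, c("subject_id",
                                  setdiff(names(d), "subject_id"))]
  structure(list(
    visits = first_cols(do.call(rbind, visits)),
    maternal = do.call(rbind, maternal),
    neonatal = first_cols(do.call(rbind, neonatal)),
    truth = first_cols(do.call(rbind, truth)),
    config = config), class = "fv_cohort")
}

#' @export
print.fv_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$maternal), "subjects,",
      nrow(x$visits), "visits\n")
  cat("class counts:",
      paste(table(factor(x$truth$true_class,
                         levels = seq_along(x$config$class_proportions))),
            collapse = " / "), "\n")
  invisible(x)
}
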