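# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

small_cohort <- function() fx("small_cohort", function()
  generate_cohort(make_fixtures("small")))

small_weekly <- function() fx("small_weekly", function()
  cohort_weekly(small_cohort()$visits))

small_zgrid <- function() fx("small_zgrid", function()
  apply_zscore_panel(small_weekly()$grid,
                     build_zscore_panel(small_weekly()$grid)))

small_zvel <- function() fx("small_zvel", function()
  outcome_long(small_zgrid(), "EFW", "z_velocity"))

small_fit3 <- function() fx("small_fit3", function()
  fit_lcmm(small_zvel(), lcmm_spec(3), n_starts = 4, seed = 11))

noiseless_cohort <- function() fx("noiseless_cohort", function()
  generate_cohort(make_fixtures("small", noiseless = TRUE)))

noiseless_weekly <- function() fx("noiseless_weekly", function()
  cohort_weekly(noiseless_cohort()$visits))

# A truth row with all subject-level variation switched off, for
# evaluating pure class curves.
pure_truth_row <- function(class_label) {
  data.frame(true_class = class_label, size_intercept = 0, b0 = 0, b1 = 0,
             s_bpd = 0, s_fl = 0,
             eff_base_EFW = 0, eff_slope_EFW = 0,
             eff_base_BPD = 0, eff_slope_BPD = 0,
             eff_base_FL = 0, eff_slope_FL = 0)
}

# Direct simulation from the latent-class linear mixed model itself
# (no trajectory/interpolation pipeline) -- the model-true oracle for
# estimation and BIC-consistency checks.
sim_lcmm_direct <- function(n, beta, pi, D, sigma2, weeks = 20:38,
                            center = 28.5, seed = 1) {
  set.seed(seed)
  u <- weeks - center
  B <- cbind(1, stats::poly(u, nrow(as.matrix(beta)) - 1L))
  Z <- cbind(1, u)
  K <- length(pi)
  cls <- sample.int(K, n, replace = TRUE, prob = pi)
  rows <- lapply(seq_len(n), function(i) {
    b <- drop(crossprod(chol(D + diag(1e-12, 2)), stats::rnorm(2)))
    y <- drop(B %*% as.matrix(beta)[, cls[i]]) + drop(Z %*% b) +
      stats::rnorm(length(u), 0, sqrt(sigma2))
    data.frame(subject_id = sprintf("d%04d", i), week = weeks, y = y)
  })
  list(data = do.call(rbind, rows), class = cls)
}

# A plausible 3-class parameter set on the z-velocity scale, reused by
# several model-true simulations.
direct_params <- function() {
  list(beta = cbind(c(0.4, 5, -4, -1.5, 0.4),
                    c(-0.05, 1.5, 1.2, 0.3, -0.2),
                    c(-0.3, -4, 3.5, 1.2, -0.3)),
       pi = c(0.15, 0.74, 0.11),
       D = matrix(c(0.25, 0.01, 0.01, 0.02), 2),
       sigma2 = 0.25)
}

# Direct simulation from the null / alternative interaction mixed model:
# z_ij = b_i + slope * group_i * (week - 19) + e_ij.
sim_z <- function(n, slope, seed, sd_b = 0.7, sd_e = 0.6) {
  set.seed(seed)
  d <- expand.grid(subject_id = seq_len(n), week = 19:38)
  g <- stats::rbinom(n, 1, 0.5)
  b <- stats::rnorm(n, 0, sd_b)
  d$z <- b[d$subject_id] + slope * g[d$subject_id] * (d$week - 19) +
    stats::rnorm(nrow(d), 0, sd_e)
  fs <- structure(list(
    name = "coin_flip",
    levels = factor(ifelse(g == 1, "heads", "tails"),
                    levels = c("tails", "heads")),
    subject_id = seq_len(n)), class = "fv_factor_spec")
  list(z = d[, c("subject_id", "week", "z")], fspec = fs)
}

expect_monotone_trace <- function(fit) {
  d <- diff(fit$loglik_trace)
  expect_gte(min(d), -1e-10 * (1 + abs(fit$loglik)))
}
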