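test_that("the marginal log-likelihood collapses to known closed forms", {
  p <- direct_params()
  sim <- sim_lcmm_direct(6, p$beta[, 2, drop = FALSE], 1, p$D, p$sigma2,
                         seed = 4)
  spec <- lcmm_spec(1)
  # K = 1, D = 0: independent Gaussian log-densities
  ll <- lcmm_loglik(sim$data, spec, p$beta[, 2, drop = FALSE], 1,
                    matrix(0, 2, 2), 0.3)
  u <- sort(unique(sim$data$week)) - 28.5
  B <- cbind(1, stats::poly(u, 4))
  mu <- drop(B %*% p$beta[, 2])
  by_subj <- split(sim$data$y, sim$data$subject_id)
  ll_direct <- sum(vapply(by_subj, function(y)
    sum(stats::dnorm(y, mu, sqrt(0.3), log = TRUE)), 1))
  expect_equal(ll, ll_direct, tolerance = 1e-10)
  # K = 2 with identical components: independent of the mixing weights
  spec2 <- lcmm_spec(2)
  bb <- cbind(p$beta[, 2], p$beta[, 2])
  l1 <- lcmm_loglik(sim$data, spec2, bb, c(0.5, 0.5), p$D, p$sigma2)
  l2 <- lcmm_loglik(sim$data, spec2, bb, c(0.9, 0.1), p$D, p$sigma2)
  expect_equal(l1, l2, tolerance = 1e-10)
  expect_error(lcmm_loglik(sim$data, spec2, bb, c(0.5, 0.5), p$D, -1),
               "sigma2")
  expect_error(lcmm_loglik(sim$data, spec2, bb, c(0.7, 0.7), p$D, 0.3),
               "simplex")
  expect_error(lcmm_loglik(sim$data, spec2, bb, c(0.5, 0.5),
                           matrix(c(1, 2, 2, 1), 2), 0.3), "semidefinite")
})

test_that("the likelihood matches a dense multivariate-normal brute force", {
  p <- direct_params()
  spec <- lcmm_spec(3)
  # 5 subjects, 6 weeks, one subject with a missing pattern
  sim <- sim_lcmm_direct(5, p$beta, p$pi, p$D, p$sigma2, weeks = 20:25,
                         seed = 9)
  d <- sim$data
  d <- d[!(d$subject_id == "d0002" & d$week %in% c(21, 24)), ]
  ll <- lcmm_loglik(d, spec, p$beta, p$pi, p$D, p$sigma2)
  # brute force: full covariance, direct determinant/solve
  grid <- sort(unique(d$week)); u <- grid - 28.5
  B <- cbind(1, stats::poly(u, 4)); Z <- cbind(1, u)
  ll_bf <- 0
  for (s in unique(d$subject_id)) {
    di <- d[d$subject_id == s, ]
    idx <- match(di$week, grid)
    Zi <- Z[idx, , drop = FALSE]
    V <- Zi %*% p$D %*% t(Zi) + p$sigma2 * diag(nrow(di))
    dens <- vapply(1:3, function(g) {
      r <- di$y - B[idx, , drop = FALSE] %*% p$beta[, g]
      exp(-0.5 * (nrow(di) * log(2 * base::pi) + log(det(V)) +
                    drop(t(r) %*% solve(V, r))))
    }, 1)
    ll_bf <- ll_bf + log(sum(p$pi * dens))
  }
  expect_equal(ll, ll_bf, tolerance = 1e-8)
})

test_that("a K=1 fit matches an independent ML linear mixed model", {
  p <- direct_params()
  sim <- sim_lcmm_direct(60, p$beta[, 2, drop = FALSE], 1, p$D, p$sigma2,
                         seed = 21)
  f1 <- fit_lcmm(sim$data, lcmm_spec(1), n_starts = 2, seed = 1)
  d <- sim$data
  grid <- sort(unique(d$week)); u <- grid - 28.5
  B <- cbind(1, stats::poly(u, 4))
  idx <- match(d$week, grid)
  d <- cbind(d, u = d$week - 28.5, p1 = B[idx, 2], p2 = B[idx, 3],
             p3 = B[idx, 4], p4 = B[idx, 5])
  lf <- lme4::lmer(y ~ p1 + p2 + p3 + p4 + (1 + u | subject_id), data = d,
                   REML = FALSE,
                   control = lme4::lmerControl(optimizer = "bobyqa"))
  expect_equal(f1$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-4)
  expect_lt(max(abs(f1$beta[, 1] - lme4::fixef(lf))), 1e-3)
  expect_monotone_trace(f1)
  # BIC bookkeeping
  expect_equal(f1$bic, -2 * f1$loglik + f1$n_params * log(f1$n_subjects))
  expect_identical(f1$n_params, 5 + 0 + 3 + 1)
})

test_that("EM recovers a well-separated model-true 3-class mixture", {
  p <- direct_params()
  sim <- sim_lcmm_direct(300, p$beta, p$pi, p$D, p$sigma2, seed = 33)
  fit <- fit_lcmm(sim$data, lcmm_spec(3), n_starts = 4, seed = 5)
  expect_true(fit$converged)
  expect_monotone_trace(fit)
  # posterior rows sum to one
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  # D symmetric PSD, sigma2 positive, pi on the simplex
  expect_equal(fit$D, t(fit$D))
  expect_gte(min(eigen(fit$D, symmetric = TRUE)$values), -1e-12)
  expect_gt(fit$sigma2, 0)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  # class recovery up to the canonical ordering
  ari <- mclust::adjustedRandIndex(fit$assignment,
                                   sim$class[match(fit$subject_id,
                                                   sprintf("d%04d", seq_along(sim$class)))])
  expect_gte(ari, 0.9)
})

test_that("fits are invariant to subject order up to canonical labels", {
  vel <- small_zvel()
  f_a <- small_fit3()
  set.seed(8)
  perm <- sample(nrow(vel))
  f_b <- fit_lcmm(vel[perm, ], lcmm_spec(3), n_starts = 4, seed = 11)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-6)
  expect_equal(f_a$pi, f_b$pi, tolerance = 1e-6)
  expect_equal(f_a$beta, f_b$beta, tolerance = 1e-4)
  ord <- match(f_a$subject_id, f_b$subject_id)
  expect_identical(f_a$assignment, f_b$assignment[ord])
})

test_that("relabelling generator classes changes nothing after ordering", {
  cfg <- make_fixtures("small")
  swapped <- sim_config(
    n_subjects = cfg$n_subjects, seed = cfg$seed,
    class_proportions = cfg$class_proportions[c(3, 2, 1)],
    class_archetypes = cfg$class_archetypes[c(3, 2, 1), ])
  coh <- generate_cohort(swapped)
  wkl <- cohort_weekly(coh$visits, parameters = "EFW")
  zg <- apply_zscore_panel(wkl$grid, build_zscore_panel(wkl$grid))
  vel <- outcome_long(zg, "EFW", "z_velocity")
  fit <- fit_lcmm(vel, lcmm_spec(3), n_starts = 4, seed = 11)
  # canonical ordering: class 1 has the highest fitted velocity at week 31
  at31 <- with(fit$class_curves, tapply(mean[week == 31], class[week == 31],
                                        identity))
  expect_identical(order(unlist(at31), decreasing = TRUE), 1:3)
})

test_that("BIC selection is consistent on model-true data", {
  p <- direct_params()
  # single-class truth: K=1 chosen in >= 90% of replicates
  wins <- 0L
  for (r in 1:10) {
    sim <- sim_lcmm_direct(100, p$beta[, 2, drop = FALSE], 1, p$D,
                           p$sigma2, seed = 100 + r)
    sel <- select_k(sim$data, lcmm_spec(), k_range = 1:2, n_starts = 2,
                    seed = r)
    wins <- wins + (sel$chosen_k == 1L)
  }
  expect_gte(wins, 9L)
  # 3-class truth: K=3 beats its neighbours
  sim3 <- sim_lcmm_direct(250, p$beta, p$pi, p$D, p$sigma2, seed = 77)
  sel3 <- select_k(sim3$data, lcmm_spec(), k_range = 2:4, n_starts = 4,
                   seed = 2)
  expect_identical(sel3$chosen_k, 3L)
  expect_true(all(diff(sel3$table$loglik) > 0))  # logL rises with K
  # trivial scan
  sel1 <- select_k(sim3$data, lcmm_spec(), k_range = 1, n_starts = 2,
                   seed = 1)
  expect_identical(sel1$chosen_k, 1L)
})

test_that("posterior diagnostics behave at the limits", {
  p <- direct_params()
  sim <- sim_lcmm_direct(40, p$beta[, 2, drop = FALSE], 1, p$D, p$sigma2,
                         seed = 3)
  f1 <- fit_lcmm(sim$data, lcmm_spec(1), n_starts = 1, seed = 1)
  rep1 <- posterior_report(f1)
  expect_equal(rep1$mean_max_posterior, 1)
  expect_equal(rep1$entropy, 1)
  # near-perfect separation: widely spaced flat classes
  beta_sep <- cbind(c(-20, 0, 0, 0, 0), c(20, 0, 0, 0, 0))
  sim2 <- sim_lcmm_direct(40, beta_sep, c(0.5, 0.5),
                          diag(c(0.1, 0.001)), 0.2, seed = 5)
  f2 <- fit_lcmm(sim2$data, lcmm_spec(2), n_starts = 2, seed = 2)
  rep2 <- posterior_report(f2)
  expect_gt(min(rep2$class_table$mean_posterior), 0.999)
  expect_equal(sum(rep2$class_table$n), 40L)
})

test_that("raw-coefficient back-transformation reproduces the curves", {
  f <- small_fit3()
  raw <- raw_coefficients(f)
  u <- f$grid - f$spec$center
  V <- outer(u, 0:4, "^")
  curves <- matrix(f$class_curves$mean, ncol = 3)
  expect_equal(unname(V %*% raw), unname(curves), tolerance = 1e-8)
})

test_that("configuration errors are raised early", {
  p <- direct_params()
  sim <- sim_lcmm_direct(5, p$beta, p$pi, p$D, p$sigma2, seed = 1)
  expect_error(fit_lcmm(sim$data, lcmm_spec(8), n_starts = 1, seed = 1),
               "more classes than subjects")
  short <- sim$data[sim$data$week %in% 20:23, ]
  expect_error(fit_lcmm(short, lcmm_spec(1), n_starts = 1, seed = 1),
               "degree")
})
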