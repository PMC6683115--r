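test_that("the ANOVA comparison matches its closed-form limits", {
  identical_groups <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- compare_continuous(identical_groups, "toy")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  sep <- list(a = c(0, 0, 0, 0) + 1e-6 * (1:4), b = c(1, 1, 1, 1) + 1e-6 * (1:4))
  expect_lt(suppressWarnings(compare_continuous(sep)$p), 1e-6)
  expect_error(compare_continuous(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(compare_continuous(list(a = c(1, 2))), "at least 2 classes")
})

test_that("null ANOVA p-values are uniform", {
  set.seed(14)
  ps <- replicate(300, {
    g <- list(a = stats::rnorm(8), b = stats::rnorm(8), c = stats::rnorm(8))
    compare_continuous(g)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the chi-square comparison and Ryan step-down behave as designed", {
  flat <- matrix(c(10, 10, 10, 10), 2, dimnames = list(c("c1", "c2"),
                                                       c("yes", "no")))
  r <- compare_categorical(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_null(r$pairwise)
  # HFD-style proportions, scaled x10 for power
  tab <- matrix(c(200, 560, 200, 980, 5360, 710), 3,
                dimnames = list(c("c1", "c2", "c3"), c("hfd", "other")))
  r2 <- compare_categorical(tab)
  expect_lt(r2$p, 0.05)
  pw <- r2$pairwise
  # full-span adjusted level: 2*0.05 / (3 * 2)
  expect_equal(pw$alpha_adj[pw$span == 3], 2 * 0.05 / (3 * 2))
  expect_equal(pw$alpha_adj[pw$span == 2], rep(2 * 0.05 / 3, 2))
  # both extreme classes differ from the middle one
  lowest <- pw[pw$span == 3, ]
  expect_true(lowest$significant)
  expect_true(all(pw$significant[pw$span == 2]))
  expect_error(compare_categorical(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Ryan step-down is coherent across spans", {
  set.seed(99)
  n_tested <- 0L
  for (rep in 1:30) {
    k <- sample(3:5, 1)
    # heterogeneous proportions so the omnibus test fires regularly
    tab <- matrix(c(stats::rpois(k, 15 + 12 * seq_len(k)) + 1,
                    stats::rpois(k, 40) + 1), k,
                  dimnames = list(paste0("c", 1:k), c("y", "n")))
    r <- compare_categorical(tab)
    pw <- r$pairwise
    if (is.null(pw)) next
    n_tested <- n_tested + 1L
    # positions of each pair in the ordered sequence
    prop <- tab[, 1] / rowSums(tab)
    ord <- rownames(tab)[order(prop)]
    pos <- function(cl) match(cl, ord)
    for (i in seq_len(nrow(pw))) {
      if (!pw$significant[i]) next
      lo <- pos(pw$class_low[i]); hi <- pos(pw$class_high[i])
      # every spanning pair must also be significant
      span_rows <- pw[pos(pw$class_low) <= lo & pos(pw$class_high) >= hi, ]
      expect_true(all(span_rows$significant))
    }
  }
  expect_gt(n_tested, 10)
})

test_that("ratio trajectories reduce to the constructed ratios", {
  g <- expand.grid(subject_id = c("a", "b"), week = 19:21,
                   parameter = c("AC", "FL", "BPD"))
  g$value <- ifelse(g$parameter == "AC", 20,
                    ifelse(g$parameter == "FL", 10, 5))
  g$log_value <- log(g$value); g$velocity <- NA
  asn <- c(a = 1, b = 1)
  r <- ratio_trajectories(g, asn)
  expect_true(all(r$mean[r$ratio == "AC/FL"] == 2))
  expect_true(all(r$mean[r$ratio == "AC/BPD"] == 4))
  # single subject per class flags a missing SD
  asn2 <- c(a = 1, b = 2)
  r2 <- ratio_trajectories(g, asn2)
  expect_true(all(is.na(r2$sd)))
})

test_that("class-1 body proportion exceeds class-2 in late gestation", {
  coh <- noiseless_cohort()
  wkl <- noiseless_weekly()
  truth <- stats::setNames(coh$truth$true_class, coh$truth$subject_id)
  r <- ratio_trajectories(wkl$grid, truth)
  acfl <- r[r$ratio == "AC/FL" & r$week %in% 30:36, ]
  m1 <- acfl$mean[acfl$class == 1]
  m2 <- acfl$mean[acfl$class == 2]
  expect_true(all(m1 > m2))
})

test_that("examiner attribution and the homogeneity test work", {
  v <- data.frame(subject_id = rep(c("a", "b"), c(3, 3)),
                  ga_weeks = rep(c(20, 24, 28), 2),
                  examiner_id = c("D1", "D1", "D2", "D2", "D1", "D2"))
  pe <- primary_examiner(v)
  expect_identical(pe[["a"]], "D1")
  expect_identical(pe[["b"]], "D2")   # tie broken by earliest visit
  # single qualifying examiner: skipped
  asn <- c(a = 1, b = 2)
  sk <- examiner_homogeneity(asn, c(a = "D1", b = "D1"), min_subjects = 1)
  expect_true(sk$skipped)
  # perfect confounding: p ~ 0
  n <- 300
  asn2 <- rep(1:3, each = n / 3)
  names(asn2) <- sprintf("s%03d", seq_len(n))
  ex2 <- stats::setNames(paste0("D", asn2), names(asn2))
  r2 <- examiner_homogeneity(asn2, ex2, min_subjects = 50)
  expect_lt(r2$p, 1e-10)
  # independence: p uniform over replicates
  set.seed(5)
  ps <- replicate(200, {
    asn3 <- sample(1:3, n, replace = TRUE, prob = c(.15, .74, .11))
    names(asn3) <- names(asn2)
    ex3 <- stats::setNames(sample(c("D1", "D2", "D3"), n, replace = TRUE),
                           names(asn2))
    suppressWarnings(examiner_homogeneity(asn3, ex3, min_subjects = 50)$p)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("examiner assignment is independent of class in the generator", {
  coh <- small_cohort()
  fitc <- small_fit3()
  asn <- stats::setNames(fitc$assignment, fitc$subject_id)
  r <- examiner_homogeneity(asn, primary_examiner(coh$visits),
                            min_subjects = 10)
  expect_false(r$skipped)
  expect_gt(r$p, 1e-4)
})

test_that("sensitivity reruns behave under empty and random exclusions", {
  coh <- small_cohort()
  vel <- small_zvel()
  full <- small_fit3()
  s0 <- sensitivity_rerun(vel, coh$maternal, coh$neonatal, character(0),
                          full, n_starts = 4, seed = 11)
  expect_identical(s0$excluded_n, 0L)
  expect_equal(s0$fit$pi, full$pi, tolerance = 1e-10)
  # ~10% excluded via a flag independent of class
  m <- coh$maternal
  set.seed(31)
  m$random_flag <- stats::runif(nrow(m)) < 0.10
  s1 <- sensitivity_rerun(vel, m, coh$neonatal, "random_flag", full,
                          n_starts = 4, seed = 11)
  expect_lt(max(abs(s1$fit$pi - full$pi)), 0.05)
  # refusal below 10 subjects per class
  m$kill <- TRUE
  m$kill[1:20] <- FALSE
  expect_error(sensitivity_rerun(vel, m, coh$neonatal, "kill", full),
               "10 subjects per class")
  expect_error(sensitivity_rerun(vel, m, coh$neonatal, "no_such_flag", full),
               "unknown exclusion flag")
})

test_that("the class comparison table covers every variable once", {
  coh <- small_cohort()
  fitc <- small_fit3()
  asn <- stats::setNames(fitc$assignment, fitc$subject_id)
  tab <- class_comparison_table(coh$maternal, coh$neonatal, asn)
  expect_identical(anyDuplicated(tab$variable), 0L)
  expect_true(all(c("maternal_age", "birthweight", "ga_delivery",
                    "sex_male", "hfd") %in% tab$variable))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  det <- attr(tab, "details")
  # per-class n sums to the cohort n for continuous rows
  expect_equal(sum(det$maternal_age$summary$n), nrow(coh$maternal))
})

test_that("the ratio mixture machinery runs end to end", {
  wkl <- small_weekly()
  sel <- lcmm_on_ratio(wkl$grid, k_range = 1:2, n_starts = 2, seed = 13)
  expect_s3_class(sel, "fv_lcmm_selection")
  expect_identical(nrow(sel$table), 2L)
  expect_true(all(is.finite(sel$table$bic)))
  # constant ratio per subject with between-subject spread: the random
  # intercept absorbs it and one class suffices (model-true check)
  set.seed(41)
  const <- do.call(rbind, lapply(1:60, function(i)
    data.frame(subject_id = i, week = 19:38,
               y = 2 + stats::rnorm(1, 0, 0.1) +
                 stats::rnorm(20, 0, 0.02))))
  selc <- select_k(const, lcmm_spec(), k_range = 1:2, n_starts = 2,
                   seed = 3)
  expect_identical(selc$chosen_k, 1L)
})
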