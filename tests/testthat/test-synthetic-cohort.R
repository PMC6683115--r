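test_that("class labels are reproducible and converge to the proportions", {
  expect_identical(sample_class_labels(10, c(1, 0, 0), seed = 4),
                   rep(1L, 10))
  l1 <- sample_class_labels(50, c(0.2, 0.5, 0.3), seed = 7)
  l2 <- sample_class_labels(50, c(0.2, 0.5, 0.3), seed = 7)
  expect_identical(l1, l2)
  big <- sample_class_labels(1e5, c(0.15, 0.74, 0.11), seed = 12)
  emp <- as.numeric(table(factor(big, levels = 1:3))) / 1e5
  expect_lt(max(abs(emp - c(0.15, 0.74, 0.11))), 0.01)
  expect_error(sample_class_labels(5, c(0.5, 0.4), seed = 1), "sum to 1")
})

test_that("labels are invariant to cohort size (hierarchical substreams)", {
  l_small <- sample_class_labels(20, c(0.3, 0.7), seed = 9)
  l_big <- sample_class_labels(200, c(0.3, 0.7), seed = 9)
  expect_identical(l_small, l_big[1:20])
})

test_that("a flat velocity archetype yields an exactly log-linear EFW", {
  cfg <- sim_config(n_subjects = 1, seed = 1, class_proportions = 1,
                    class_archetypes = matrix(c(0.12, 0, 0, 0, 0), 1),
                    size_sd = 0, random_intercept_sd = 0,
                    random_slope_sd = 0, delivery_mean = 39.3,
                    delivery_sd = 1)
  tr <- data.frame(true_class = 1L, size_intercept = 0, b0 = 0, b1 = 0,
                   eff_base_EFW = 0, eff_slope_EFW = 0)
  t <- seq(15, 38, by = 0.5)
  lv <- true_log_efw(t, tr, cfg)
  expect_equal(diff(lv), rep(0.12 * 0.5, length(t) - 1), tolerance = 1e-12)
  # the analytic weekly natural-scale difference
  wk <- 19:38
  efw <- exp(true_log_efw(wk, tr, cfg))
  expect_equal(diff(efw) / efw[-length(wk)], rep(exp(0.12) - 1, 19),
               tolerance = 1e-12)
})

test_that("the checkup schedule enumerates the expected visit weeks", {
  cfg <- sim_config(n_subjects = 1, seed = 1)
  planned <- fetalvelo:::.planned_visits(12, 39, cfg)
  expect_equal(planned, c(12, 16, 20, 24, 26, 28, 30, 32, 34, 36, 37, 38, 39))
  expect_gte(length(planned), 10)
  expect_lte(length(planned), 13)
  # spacing honours the 4 / 2 / 1 week regimen
  expect_true(all(diff(planned) %in% c(4, 2, 1)))
})

test_that("noiseless biometry reproduces the true EFW through the formula", {
  cfg <- sim_config(n_subjects = 2, seed = 3)
  for (g in 1:3) {
    tr <- pure_truth_row(g)
    t <- seq(12, 40, by = 0.25)
    bio <- fetalvelo:::.true_biometry(t, tr, cfg)
    expect_true(all(bio$ac > 0 & bio$bpd > 0 & bio$fl > 0))
    rel <- abs(compute_efw(bio$bpd, bio$ac, bio$fl) - bio$efw) / bio$efw
    expect_lt(max(rel), 0.005)
  }
})

test_that("class archetypes reproduce the described velocity orderings", {
  cfg <- sim_config(n_subjects = 1, seed = 1)
  wk <- 19:38
  efw <- sapply(1:3, function(g) exp(true_log_efw(wk, pure_truth_row(g), cfg)))
  v <- apply(efw, 2, diff)            # natural velocity, weeks 20..38
  vw <- 20:38
  in_range <- function(a, b) vw >= a & vw <= b
  expect_true(all(v[in_range(28, 32), 1] > v[in_range(28, 32), 2]))
  expect_true(all(v[in_range(37, 38), 1] < v[in_range(37, 38), 2]))
  expect_true(all(v[in_range(24, 26), 3] < v[in_range(24, 26), 2]))
  expect_true(all(v[in_range(37, 38), 3] > v[in_range(37, 38), 2]))
  # class 1: acceleration peak within weeks 30-33
  expect_true(vw[which.max(v[, 1])] %in% 30:33)
  # class 2: monotone acceleration through week 30
  expect_true(all(diff(v[vw <= 30, 2]) > 0))
})

test_that("cohort generation is deterministic and order-invariant", {
  c1 <- generate_cohort(sim_config(n_subjects = 20, seed = 99))
  c2 <- generate_cohort(sim_config(n_subjects = 20, seed = 99))
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(sim_config(n_subjects = 25, seed = 99))
  expect_identical(c1$visits$ga_weeks,
                   c3$visits$ga_weeks[c3$visits$subject_id %in%
                                        c1$visits$subject_id])
  c4 <- generate_cohort(sim_config(n_subjects = 20, seed = 100))
  expect_false(identical(c1$visits$bpd_cm, c4$visits$bpd_cm))
  one <- generate_cohort(sim_config(n_subjects = 1, seed = 5))
  expect_identical(nrow(one$maternal), 1L)
  expect_identical(nrow(one$truth), 1L)
  expect_error(sim_config(n_subjects = 0), "n_subjects")
})

test_that("the default cohort passes the inclusion funnel by construction", {
  coh <- small_cohort()
  fun <- apply_inclusion_criteria(coh$visits, coh$maternal, coh$neonatal)
  expect_identical(length(fun$ids), nrow(coh$maternal))
  # visit invariants: positive biometry, orderable, no duplicate weeks
  expect_true(all(coh$visits$bpd_cm > 0 & coh$visits$ac_cm > 0 &
                    coh$visits$fl_cm > 0))
  dup <- tapply(coh$visits$ga_weeks, coh$visits$subject_id,
                function(g) any(duplicated(g)))
  expect_false(any(dup))
})

test_that("generated covariate effects reproduce the expected z-gap shapes", {
  coh <- noiseless_cohort()
  wkl <- noiseless_weekly()
  zg <- apply_zscore_panel(wkl$grid, build_zscore_panel(wkl$grid))
  sex <- stats::setNames(coh$neonatal$sex_male, coh$neonatal$subject_id)
  g <- zg[zg$parameter == "EFW", ]
  g$male <- sex[as.character(g$subject_id)]
  gap <- tapply(g$z_value[g$male], g$week[g$male], mean) -
    tapply(g$z_value[!g$male], g$week[!g$male], mean)
  # male advantage at 19 weeks shrinks through late gestation
  expect_gt(gap[["19"]], gap[["30"]])
  expect_gt(gap[["30"]], gap[["38"]])
  expect_gt(gap[["19"]], 0)
  bmi <- stats::setNames(coh$maternal$prepreg_bmi, coh$maternal$subject_id)
  a <- zg[zg$parameter == "AC", ]
  grp <- cut(bmi[as.character(a$subject_id)], c(-Inf, 18.5, 25, Inf),
             labels = c("Lean", "Normal", "Overweight"), right = FALSE)
  gapB <- tapply(a$z_value[grp == "Overweight"], a$week[grp == "Overweight"],
                 mean) -
    tapply(a$z_value[grp == "Lean"], a$week[grp == "Lean"], mean)
  expect_true(all(diff(gapB) > 0))  # monotone growth from 19 to 38
})

test_that("neonatal size categories are consistent with the percentiles", {
  n <- small_cohort()$neonatal
  expect_true(all(n$weight_pct >= 0 & n$weight_pct <= 100))
  expect_true(all(n$size_category[n$weight_pct >= 90] == "HFD"))
  expect_true(all(n$weight_pct[n$size_category %in% c("LFD", "SGA")] <= 10))
  expect_true(all(n$length_pct[n$size_category == "SGA"] <= 10))
  expect_true(all(n$size_category %in% c("AGA", "HFD", "LFD", "SGA")))
})
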