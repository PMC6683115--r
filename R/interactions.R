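#' Specification of a tested growth-associated factor
#'
#' Builds the factor levels tested for week-varying effects on weekly
#' z-scores: fetal sex, maternal height quartile, pre-pregnancy BMI group
#' (<18.5 / 18.5--25 / >25), parity, and maternal age decade.
#'
#' @param name one of `"fetal_sex"`, `"maternal_height_quartile"`,
#'   `"prepreg_bmi_group"`, `"parity"`, `"maternal_age_group"`.
#' @param maternal,neonatal cohort tables (quartile edges are computed
#'   from the cohort).
#' @return list of class `fv_factor_spec`: `name`, `levels` (factor per
#'   subject, reference level first), `subject_id`.
#' @export
factor_spec <- function(name = c("fetal_sex", "maternal_height_quartile",
                                 "prepreg_bmi_group", "parity",
                                 "maternal_age_group"),
                        maternal, neonatal) {
  name <- match.arg(name)
  sid <- maternal$subject_id
  lv <- switch(name,
    fetal_sex = {
      s <- neonatal$sex_male[match(sid, neonatal$subject_id)]
      factor(ifelse(s, "male", "female"), levels = c("female", "male"))
    },
    maternal_height_quartile = {
      q <- stats::quantile(maternal$height_cm, c(0.25, 0.5, 0.75))
      cut(maternal$height_cm, c(-Inf, q, Inf),
          labels = c("Q1", "Q2", "Q3", "Q4"))
    },
    prepreg_bmi_group = {
      g <- cut(maternal$prepreg_bmi, c(-Inf, 18.5, 25, Inf),
               labels = c("Lean", "Normal", "Overweight"), right = FALSE)
      # boundary conventions: 18.5 <= BMI <= 25 is Normal
      g[maternal$prepreg_bmi == 25] <- "Normal"
      factor(g, levels = c("Normal", "Lean", "Overweight"))
    },
    parity = factor(ifelse(maternal$parity_multiparous, "multiparous",
                           "nulliparous"),
                    levels = c("nulliparous", "multiparous")),
    maternal_age_group = {
      g <- cut(maternal$age_years, c(-Inf, 30, 40, Inf),
               labels = c("20s", "30s", "40s"), right = FALSE)
      factor(g, levels = c("30s", "20s", "40s"))
    })
  if (nlevels(droplevels(lv)) < 2)
    stop("factor '", name, "' is constant in this cohort", call. = FALSE)
  structure(list(name = name, levels = lv, subject_id = sid),
            class = "fv_factor_spec")
}

#' Test a factor-by-week interaction on weekly z-scores
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `z ~ factor * week_c + (1 | subject)` where `week_c` is gestational
#' week centered at 19 (so the factor main effects are week-19 contrasts),
#' and reports a Wald test with Satterthwaite denominator degrees of
#' freedom for each non-reference level's interaction coefficient
#' (z-units per week). A level is flagged significant when its p-value is
#' below `p_threshold` and the absolute coefficient exceeds
#' `effect_threshold`.
#'
#' @param z_long data.frame `subject_id`, `week`, `z` for one outcome
#'   parameter.
#' @param fspec an [fv_factor_spec][factor_spec()].
#' @param outcome label for the tested parameter (reporting only).
#' @param p_threshold Bonferroni-corrected significance level (default
#'   2.7e-4).
#' @param effect_threshold minimum absolute interaction coefficient in
#'   z-units per week (default 0.01).
#' @param ddf denominator-degrees-of-freedom method passed to lmerTest.
#' @return data.frame of class `fv_interaction`: one row per non-reference
#'   level with estimate, SE, df, t, p and the significance flag; carries
#'   the fitted model in attribute `"model"`.
#' @export
fit_interaction_model <- function(z_long, fspec, outcome = "EFW",
                                  p_threshold = 2.7e-4,
                                  effect_threshold = 0.01,
                                  ddf = c("Satterthwaite", "Kenward-Roger")) {
  ddf <- match.arg(ddf)
  d <- z_long[!is.na(z_long$z), , drop = FALSE]
  d$level <- fspec$levels[match(d$subject_id, fspec$subject_id)]
  d <- d[!is.na(d$level), , drop = FALSE]
  d$level <- droplevels(d$level)
  if (nlevels(d$level) < 2)
    stop("factor '", fspec$name, "' has fewer than 2 populated levels",
         call. = FALSE)
  d$week_c <- d$week - 19
  fit <- lmerTest::lmer(z ~ level * week_c + (1 | subject_id), data = d,
                        REML = FALSE)
  conv <- fit@optinfo$conv$lme4
  converged <- is.null(conv$messages) ||
    !any(grepl("failed to converge", conv$messages))
  co <- summary(fit, ddf = ddf)$coefficients
  rows <- grep("^level.*:week_c$", rownames(co))
  lev <- sub(":week_c$", "", sub("^level", "", rownames(co)[rows]))
  out <- data.frame(
    outcome = outcome, factor = fspec$name, level = lev,
    estimate = co[rows, "Estimate"], se = co[rows, "Std. Error"],
    df = co[rows, "df"], t = co[rows, "t value"],
    p = co[rows, "Pr(>|t|)"],
    converged = converged)
  out$significant <- out$p < p_threshold &
    abs(out$estimate) > effect_threshold
  rownames(out) <- NULL
  attr(out, "model") <- fit
  class(out) <- c("fv_interaction", "data.frame")
  out
}

#' Descriptive weekly mean +/- SD curves per factor level
#'
#' @param z_long data.frame `subject_id`, `week`, `z`.
#' @param fspec an [fv_factor_spec][factor_spec()].
#' @return data.frame `level`, `week`, `mean`, `sd` (SD is `NA` for
#'   single-subject cells), `n`.
#' @export
summarize_factor_trajectories <- function(z_long, fspec) {
  d <- z_long[!is.na(z_long$z), , drop = FALSE]
  d$level <- fspec$levels[match(d$subject_id, fspec$subject_id)]
  d <- d[!is.na(d$level), , drop = FALSE]
  agg <- stats::aggregate(d$z, by = list(level = d$level, week = d$week),
                          FUN = function(v) c(mean(v),
                                              if (length(v) > 1)
                                                stats::sd(v) else NA_real_,
                                              length(v)))
  out <- data.frame(level = agg$level, week = agg$week,
                    mean = agg$x[, 1], sd = agg$x[, 2], n = agg$x[, 3])
  out[order(out$level, out$week), ]
}

#' Run every factor x outcome interaction test
#'
#' Applies [fit_interaction_model()] across the five factors and the
#' requested outcome parameters, collecting one results table. The number
#' of tests performed is recorded in attribute `"n_tests"` so the
#' Bonferroni accounting is explicit.
#'
#' @param zgrid standardized grid from [apply_zscore_panel()].
#' @param maternal,neonatal cohort tables.
#' @param outcomes parameters to test.
#' @param factors factor names to test.
#' @param ... passed to [fit_interaction_model()].
#' @return combined data.frame of per-level results.
#' @export
interaction_screen <- function(zgrid, maternal, neonatal,
                               outcomes = c("EFW", "BPD", "AC", "FL"),
                               factors = c("fetal_sex",
                                           "maternal_height_quartile",
                                           "prepreg_bmi_group", "parity",
                                           "maternal_age_group"), ...) {
  res <- list()
  for (f in factors) {
    fs <- factor_spec(f, maternal, neonatal)
    for (p in outcomes) {
      g <- zgrid[zgrid$parameter == p, , drop = FALSE]
      zl <- data.frame(subject_id = g$subject_id, week = g$week,
                       z = g$z_value)
      r <- fit_interaction_model(zl, fs, outcome = p, ...)
      attr(r, "model") <- NULL
      res[[paste(f, p)]] <- r
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}
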