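#' One-way ANOVA comparison of a continuous variable across classes
#'
#' @param values_by_class named list of numeric vectors, one per class.
#' @param variable label for reporting.
#' @return list of class `fv_comparison`: per-class `n`, `mean`, `sd`,
#'   F statistic, p-value.
#' @export
compare_continuous <- function(values_by_class, variable = "variable") {
  k <- length(values_by_class)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  ns <- vapply(values_by_class, function(v) sum(!is.na(v)), 1L)
  if (any(ns < 2))
    stop("class with fewer than 2 observations: ",
         paste(names(values_by_class)[ns < 2], collapse = ", "),
         call. = FALSE)
  d <- data.frame(
    y = unlist(values_by_class, use.names = FALSE),
    g = factor(rep(seq_len(k), times = vapply(values_by_class, length, 1L))))
  d <- d[!is.na(d$y), ]
  a <- stats::anova(stats::aov(y ~ g, data = d))
  structure(list(
    variable = variable, test = "one-way ANOVA",
    summary = data.frame(class = names(values_by_class), n = ns,
                         mean = vapply(values_by_class, mean, 1,
                                       na.rm = TRUE),
                         sd = vapply(values_by_class, stats::sd, 1,
                                     na.rm = TRUE)),
    statistic = a$`F value`[1], p = a$`Pr(>F)`[1]),
    class = "fv_comparison")
}

#' Chi-square comparison of a categorical variable across classes, with
#' Ryan's step-down pairwise procedure for proportions
#'
#' Runs the omnibus chi-square test on the classes x levels table. For a
#' two-level outcome, if the omnibus test is significant at `alpha`, the
#' classes are ordered by proportion and pairs are tested step-down, each
#' pair at Ryan's adjusted level \eqn{\alpha' = 2\alpha/(k(r-1))} where
#' \eqn{k} is the number of classes and \eqn{r} the span of the ordered
#' pair; a pair is only examined when every pair spanning it was
#' significant, so the step-down scheme is coherent by construction.
#' Pairwise tests use the chi-square statistic without continuity
#' correction, the same family as the omnibus test.
#'
#' @param counts_by_class matrix (classes x levels) of counts, with
#'   dimnames.
#' @param variable label for reporting.
#' @param alpha omnibus and Ryan base level.
#' @return list of class `fv_comparison` with `statistic`, `p`, per-class
#'   summary, and `pairwise` (Ryan decisions; `NULL` when not applicable).
#' @export
compare_categorical <- function(counts_by_class, variable = "variable",
                                alpha = 0.05) {
  tab <- as.matrix(counts_by_class)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table: zero marginal", call. = FALSE)
  k <- nrow(tab)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  pairwise <- NULL
  if (ncol(tab) == 2L && k >= 2 && chi$p.value < alpha) {
    prop <- tab[, 1] / rowSums(tab)
    ord <- order(prop)
    res <- list()
    # examine spans from widest to narrowest; prune non-coherent pairs
    sig <- matrix(NA, k, k)
    for (r in seq(k, 2)) {
      for (i in seq_len(k - r + 1)) {
        j <- i + r - 1
        # a (i,j) pair is only tested when the pairs spanning it were
        # significant: all (a,b) with a <= i, b >= j, (a,b) != (i,j)
        spanning <- expand.grid(a = seq_len(i), b = j:k)
        spanning <- spanning[!(spanning$a == i & spanning$b == j), ,
                             drop = FALSE]
        eligible <- nrow(spanning) == 0 ||
          all(vapply(seq_len(nrow(spanning)), function(s)
            isTRUE(sig[spanning$a[s], spanning$b[s]]), TRUE))
        if (!eligible) { sig[i, j] <- FALSE; next }
        sub <- tab[ord[c(i, j)], , drop = FALSE]
        p_pair <- suppressWarnings(
          stats::chisq.test(sub, correct = FALSE)$p.value)
        a_adj <- 2 * alpha / (k * (r - 1))
        sig[i, j] <- is.finite(p_pair) && p_pair < a_adj
        res[[length(res) + 1L]] <- data.frame(
          class_low = rownames(tab)[ord[i]],
          class_high = rownames(tab)[ord[j]],
          span = r, p = p_pair, alpha_adj = a_adj,
          significant = sig[i, j], tested = TRUE)
      }
    }
    pairwise <- do.call(rbind, res)
  }
  structure(list(
    variable = variable, test = "chi-square (Ryan pairwise)",
    summary = data.frame(class = rownames(tab),
                         n = unname(rowSums(tab)),
                         as.data.frame.matrix(tab, row.names = NULL),
                         check.names = FALSE, row.names = NULL),
    statistic = unname(chi$statistic), p = chi$p.value,
    pairwise = pairwise), class = "fv_comparison")
}

#' @export
print.fv_comparison <- function(x, ...) {
  cat(x$variable, "--", x$test, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("statistic = %.4g, p = %.3g\n", x$statistic, x$p))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Per-class mean body-proportion trajectories
#'
#' Computes each subject's weekly AC/FL and AC/BPD ratios from
#' natural-scale weekly values, then per-class weekly means and SDs.
#'
#' @param grid long weekly grid from [cohort_weekly()] (needs AC, FL,
#'   BPD).
#' @param assignment named vector (or data.frame `subject_id`, `class`)
#'   mapping subjects to classes.
#' @return data.frame `ratio`, `class`, `week`, `mean`, `sd`, `n`.
#' @export
ratio_trajectories <- function(grid, assignment) {
  if (is.data.frame(assignment))
    assignment <- stats::setNames(assignment$class, assignment$subject_id)
  wide <- stats::reshape(
    grid[, c("subject_id", "parameter", "week", "value")],
    idvar = c("subject_id", "week"), timevar = "parameter",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  out <- list()
  for (rt in c("AC/FL", "AC/BPD")) {
    den <- if (rt == "AC/FL") wide$FL else wide$BPD
    ratio <- wide$AC / den
    keep <- !is.na(ratio)
    d <- data.frame(week = wide$week[keep], ratio = ratio[keep],
                    class = assignment[as.character(wide$subject_id[keep])])
    d <- d[!is.na(d$class), ]
    agg <- stats::aggregate(d$ratio, by = list(class = d$class,
                                               week = d$week),
                            FUN = function(v) c(mean(v),
                                                if (length(v) > 1)
                                                  stats::sd(v) else NA_real_,
                                                length(v)))
    out[[rt]] <- data.frame(ratio = rt, class = agg$class, week = agg$week,
                            mean = agg$x[, 1], sd = agg$x[, 2],
                            n = agg$x[, 3])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$ratio, res$class, res$week), ]
}

#' Primary examiner of each subject
#'
#' The examiner with the most visits for the subject; ties go to the
#' examiner seen earliest.
#'
#' @param visits visits table with `examiner_id`.
#' @return named character vector (subject -> examiner).
#' @export
primary_examiner <- function(visits) {
  vapply(split(visits, visits$subject_id), function(d) {
    d <- d[order(d$ga_weeks), ]
    cnt <- table(d$examiner_id)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) == 1L) top else
      as.character(d$examiner_id[match(TRUE, d$examiner_id %in% top)])
  }, "")
}

#' Homogeneity of class distribution across examiners
#'
#' Chi-square test on the examiner x class table, restricted to examiners
#' who were the primary examiner of at least `min_subjects` subjects.
#'
#' @param assignment named class vector (subject -> class).
#' @param examiner_of_subject named examiner vector (subject -> examiner),
#'   e.g. from [primary_examiner()].
#' @param min_subjects examiner inclusion threshold (default 100).
#' @return list with `table`, `statistic`, `p`, `examiners`; or a skipped
#'   marker (`skipped = TRUE`, `reason`) when fewer than 2 examiners
#'   qualify.
#' @export
examiner_homogeneity <- function(assignment, examiner_of_subject,
                                 min_subjects = 100) {
  sid <- intersect(names(assignment), names(examiner_of_subject))
  ex <- examiner_of_subject[sid]
  counts <- table(ex)
  qual <- names(counts)[counts >= min_subjects]
  if (length(qual) < 2)
    return(list(skipped = TRUE,
                reason = paste0("fewer than 2 examiners with >= ",
                                min_subjects, " subjects")))
  keep <- ex %in% qual
  tab <- table(examiner = ex[keep], class = assignment[sid][keep])
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(skipped = FALSE, table = tab, statistic = unname(chi$statistic),
       p = chi$p.value, examiners = qual)
}

#' Refit the latent-class model on a sensitivity subset
#'
#' Excludes subjects flagged on any of the named maternal/neonatal flag
#' fields and refits the latent-class model with identical settings,
#' reporting class proportions and mean trajectories next to the
#' full-cohort fit (matched by the canonical class ordering).
#'
#' @param velocity_long outcome series (`subject_id`, `week`, `y`).
#' @param maternal,neonatal cohort tables carrying the flag fields.
#' @param exclude_flags character vector of logical columns; a subject is
#'   excluded when any named flag is `TRUE`. For `"preterm"` the rule
#'   `ga_delivery_weeks < 37` is applied to the neonatal table.
#' @param full_fit the full-cohort `fv_lcmm` to compare against.
#' @param ... passed to [fit_lcmm()].
#' @return list of class `fv_sensitivity`: `fit`, `excluded_n`,
#'   `comparison` (class, pi_full, pi_subset).
#' @export
sensitivity_rerun <- function(velocity_long, maternal, neonatal,
                              exclude_flags, full_fit, ...) {
  drop_ids <- character(0)
  for (fl in exclude_flags) {
    if (fl == "preterm") {
      drop_ids <- c(drop_ids,
                    neonatal$subject_id[neonatal$ga_delivery_weeks < 37])
    } else if (fl %in% names(maternal)) {
      drop_ids <- c(drop_ids, maternal$subject_id[isTRUE_vec(maternal[[fl]])])
    } else if (fl %in% names(neonatal)) {
      drop_ids <- c(drop_ids, neonatal$subject_id[isTRUE_vec(neonatal[[fl]])])
    } else {
      stop("unknown exclusion flag '", fl, "'", call. = FALSE)
    }
  }
  drop_ids <- unique(drop_ids)
  keep <- !(velocity_long$subject_id %in% drop_ids)
  sub <- velocity_long[keep, , drop = FALSE]
  K <- full_fit$spec$n_classes
  if (length(unique(sub$subject_id)) < 10 * K)
    stop("sensitivity subset smaller than 10 subjects per class",
         call. = FALSE)
  fit <- fit_lcmm(sub, full_fit$spec, ...)
  structure(list(
    fit = fit, excluded_n = length(drop_ids),
    comparison = data.frame(class = seq_len(K), pi_full = full_fit$pi,
                            pi_subset = fit$pi)),
    class = "fv_sensitivity")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.fv_sensitivity <- function(x, ...) {
  cat("Sensitivity refit: excluded", x$excluded_n, "subjects\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Latent-class analysis of the AC/FL body-proportion trajectory
#'
#' Reuses the latent-class machinery on the weekly AC/FL ratio (a size
#' scale, not a velocity), scanning class counts 1..5 by default.
#'
#' @param grid long weekly grid from [cohort_weekly()] (needs AC and FL).
#' @param spec base [lcmm_spec()] (its `n_classes` is overridden by the
#'   scan).
#' @param k_range candidate class counts.
#' @param ... passed to [select_k()].
#' @return an `fv_lcmm_selection`.
#' @export
lcmm_on_ratio <- function(grid, spec = lcmm_spec(), k_range = 1:5, ...) {
  ac <- grid[grid$parameter == "AC", c("subject_id", "week", "value")]
  fl <- grid[grid$parameter == "FL", c("subject_id", "week", "value")]
  m <- merge(ac, fl, by = c("subject_id", "week"),
             suffixes = c("_ac", "_fl"))
  ratio <- data.frame(subject_id = m$subject_id, week = m$week,
                      y = m$value_ac / m$value_fl)
  select_k(ratio[!is.na(ratio$y), ], spec, k_range = k_range, ...)
}

#' Class-wise comparison table for maternal and neonatal characteristics
#'
#' Builds the standard descriptive comparison: ANOVA for continuous
#' variables, chi-square (with Ryan pairwise tests for binary variables)
#' for categorical ones, one row per variable.
#'
#' @param maternal,neonatal cohort tables.
#' @param assignment named class vector (subject -> class).
#' @return data.frame `variable`, `type`, `statistic`, `p`; the full
#'   comparison objects are in attribute `"details"`.
#' @export
class_comparison_table <- function(maternal, neonatal, assignment) {
  cls <- assignment[as.character(maternal$subject_id)]
  classes <- sort(unique(cls))
  split_by <- function(x, ids) {
    cl <- assignment[as.character(ids)]
    lapply(stats::setNames(classes, paste0("class", classes)),
           function(g) x[!is.na(cl) & cl == g])
  }
  cont <- list(
    maternal_age = list(maternal$age_years, maternal$subject_id),
    maternal_height = list(maternal$height_cm, maternal$subject_id),
    prepreg_weight = list(maternal$prepreg_weight_kg, maternal$subject_id),
    prepreg_bmi = list(maternal$prepreg_bmi, maternal$subject_id),
    ga_delivery = list(neonatal$ga_delivery_weeks, neonatal$subject_id),
    birthweight = list(neonatal$birthweight_g, neonatal$subject_id),
    birth_length = list(neonatal$length_cm, neonatal$subject_id),
    head_circumference = list(neonatal$head_circ_cm, neonatal$subject_id),
    chest_circumference = list(neonatal$chest_circ_cm, neonatal$subject_id),
    weight_percentile = list(neonatal$weight_pct, neonatal$subject_id),
    length_percentile = list(neonatal$length_pct, neonatal$subject_id),
    head_percentile = list(neonatal$head_pct, neonatal$subject_id),
    placenta_weight = list(neonatal$placenta_g, neonatal$subject_id))
  cat_vars <- list(
    sex_male = list(neonatal$sex_male, neonatal$subject_id),
    parity_multiparous = list(maternal$parity_multiparous,
                              maternal$subject_id),
    poor_obstetric_history = list(maternal$poor_obstetric_history,
                                  maternal$subject_id),
    complications = list(maternal$complications, maternal$subject_id),
    disease_history = list(maternal$disease_history, maternal$subject_id),
    assisted_conception = list(maternal$assisted_conception,
                               maternal$subject_id),
    smoking_pre = list(maternal$smoking_pre, maternal$subject_id),
    smoking_during = list(maternal$smoking_during, maternal$subject_id),
    hfd = list(neonatal$size_category == "HFD", neonatal$subject_id),
    lfd = list(neonatal$size_category == "LFD", neonatal$subject_id),
    sga = list(neonatal$size_category == "SGA", neonatal$subject_id))
  details <- list(); rows <- list()
  for (v in names(cont)) {
    cmp <- compare_continuous(split_by(cont[[v]][[1]], cont[[v]][[2]]), v)
    details[[v]] <- cmp
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            statistic = cmp$statistic, p = cmp$p)
  }
  for (v in names(cat_vars)) {
    x <- cat_vars[[v]][[1]]; ids <- cat_vars[[v]][[2]]
    cl <- assignment[as.character(ids)]
    tab <- table(class = cl, value = factor(x, levels = c(TRUE, FALSE)))
    cmp <- tryCatch(compare_categorical(tab, v),
                    error = function(e) NULL)
    if (is.null(cmp)) next
    details[[v]] <- cmp
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            statistic = cmp$statistic, p = cmp$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
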