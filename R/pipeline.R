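#' Write a cohort's interchange tables to a directory
#'
#' Emits `visits.csv`, `maternal.csv`, `neonatal.csv` (UTF-8, header row,
#' empty cells for missing values) plus, for synthetic cohorts,
#' `truth.csv` and a flat key-value `config_echo.txt`.
#'
#' @param cohort an `fv_cohort` (or a plain list with the three tables).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE, na = "")
  wr(cohort$visits, "visits.csv")
  wr(cohort$maternal, "maternal.csv")
  wr(cohort$neonatal, "neonatal.csv")
  if (!is.null(cohort$truth))
    wr(cohort$truth[, c("subject_id", "true_class")], "truth.csv")
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    lines <- vapply(names(cfg), function(nm) {
      v <- cfg[[nm]]
      val <- if (is.matrix(v)) paste(signif(t(v), 10), collapse = " ")
        else if (is.list(v)) "<nested>"
        else paste(format(v, digits = 10), collapse = " ")
      paste0(nm, ": ", val)
    }, "")
    writeLines(lines, file.path(dir, "config_echo.txt"))
  }
  invisible(dir)
}

#' Read cohort interchange tables from a directory
#'
#' @param dir directory holding `visits.csv`, `maternal.csv`,
#'   `neonatal.csv`.
#' @return list with the three data.frames.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input table: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(visits = rd("visits.csv"), maternal = rd("maternal.csv"),
       neonatal = rd("neonatal.csv"))
}

#' End-to-end analysis pipeline
#'
#' Runs funnel -> weekly trajectories -> z-scores -> interaction screen ->
#' latent-class selection -> class profiles -> sensitivity reruns on
#' either a synthetic cohort (when `sim` is given) or tables read from
#' `input_dir`, writing every stage's tables plus a JSON manifest under
#' `out_dir`.
#'
#' @param sim an [sim_config()] for synthetic mode, or `NULL` to read
#'   `input_dir`.
#' @param input_dir directory with visits/maternal/neonatal CSVs
#'   (real-data mode).
#' @param out_dir output directory; created if needed. `NULL` skips
#'   writing.
#' @param parameters biometry parameters to interpolate.
#' @param weeks integer analysis grid.
#' @param k_range latent-class counts to scan.
#' @param n_starts EM starts per class count.
#' @param seed seed for the latent-class fits.
#' @param run_interactions,run_profiles,run_sensitivity stage switches
#'   (useful for quick runs).
#' @param sensitivity_flags exclusion lists for the sensitivity reruns.
#' @return list of class `fv_pipeline` with every stage's result and the
#'   manifest.
#' @export
run_pipeline <- function(sim = NULL, input_dir = NULL, out_dir = NULL,
                         parameters = c("EFW", "BPD", "AC", "FL"),
                         weeks = 19:38, k_range = 1:4, n_starts = 20,
                         seed = 1, run_interactions = TRUE,
                         run_profiles = TRUE, run_sensitivity = FALSE,
                         sensitivity_flags = list(
                           metabolic = c("disease_history"),
                           preterm = c("preterm"),
                           lbw_risk = c("smoking_during",
                                        "poor_obstetric_history",
                                        "complications"))) {
  if (is.null(sim) && is.null(input_dir))
    stop("either a sim config or an input directory is required",
         call. = FALSE)
  cohort <- if (!is.null(sim)) generate_cohort(sim) else read_cohort(input_dir)

  funnel <- apply_inclusion_criteria(cohort$visits, cohort$maternal,
                                     cohort$neonatal)
  weekly <- cohort_weekly(funnel$visits, parameters, weeks)
  panel <- build_zscore_panel(weekly$grid)
  zgrid <- apply_zscore_panel(weekly$grid, panel)

  interactions <- NULL
  if (run_interactions)
    interactions <- interaction_screen(zgrid, funnel$maternal,
                                       funnel$neonatal,
                                       outcomes = parameters)

  vel <- outcome_long(zgrid, "EFW", "z_velocity")
  selection <- select_k(vel, lcmm_spec(), k_range = k_range,
                        n_starts = n_starts, seed = seed)
  fit <- selection$best
  prep <- posterior_report(fit)
  assignment <- stats::setNames(fit$assignment, fit$subject_id)

  profiles <- NULL; ratios <- NULL; examiner <- NULL
  if (run_profiles && fit$spec$n_classes >= 2) {
    profiles <- class_comparison_table(funnel$maternal, funnel$neonatal,
                                       assignment)
    if (all(c("AC", "FL", "BPD") %in% parameters))
      ratios <- ratio_trajectories(weekly$grid, assignment)
    if ("examiner_id" %in% names(funnel$visits))
      examiner <- examiner_homogeneity(assignment,
                                       primary_examiner(funnel$visits))
  }

  sensitivity <- NULL
  if (run_sensitivity && fit$spec$n_classes >= 2) {
    sensitivity <- lapply(sensitivity_flags, function(flags)
      tryCatch(sensitivity_rerun(vel, funnel$maternal, funnel$neonatal,
                                 flags, fit, n_starts = max(2, n_starts %/% 4),
                                 seed = seed),
               error = function(e) list(skipped = conditionMessage(e))))
  }

  manifest <- list(
    mode = if (!is.null(sim)) "synthetic" else "real",
    seed = seed,
    n_assessed = funnel$report$n_remaining[1],
    n_eligible = length(funnel$ids),
    n_interpolated = length(unique(weekly$grid$subject_id)),
    grid = range(weeks),
    chosen_k = selection$chosen_k,
    class_proportions = as.numeric(fit$pi),
    mean_max_posterior = prep$mean_max_posterior,
    stage_rows = list(visits = nrow(cohort$visits),
                      weekly = nrow(weekly$grid),
                      interactions = if (is.null(interactions)) 0L
                        else nrow(interactions)))

  out <- structure(list(
    cohort = cohort, funnel = funnel, weekly = weekly, panel = panel,
    zgrid = zgrid, interactions = interactions, selection = selection,
    fit = fit, posterior_report = prep, assignment = assignment,
    profiles = profiles, ratios = ratios, examiner = examiner,
    sensitivity = sensitivity, manifest = manifest),
    class = "fv_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(funnel$report, file.path(out_dir, "funnel.csv"),
                     row.names = FALSE)
    utils::write.csv(zgrid, file.path(out_dir, "weekly_z.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(panel), file.path(out_dir, "zpanel.csv"),
                     row.names = FALSE)
    if (!is.null(interactions))
      utils::write.csv(interactions, file.path(out_dir, "interactions.csv"),
                       row.names = FALSE)
    utils::write.csv(selection$table, file.path(out_dir, "bic_table.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$class_curves,
                     file.path(out_dir, "class_curves.csv"),
                     row.names = FALSE)
    post <- data.frame(subject_id = fit$subject_id, class = fit$assignment,
                       fit$posterior, check.names = FALSE)
    names(post)[-(1:2)] <- paste0("posterior_", seq_len(ncol(fit$posterior)))
    utils::write.csv(post, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
    if (!is.null(profiles))
      utils::write.csv(profiles, file.path(out_dir, "class_comparisons.csv"),
                       row.names = FALSE)
    if (!is.null(ratios))
      utils::write.csv(ratios, file.path(out_dir, "ratio_trajectories.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.fv_pipeline <- function(x, ...) {
  cat("Pipeline run (", x$manifest$mode, " mode)\n", sep = "")
  cat("eligible:", x$manifest$n_eligible, "of", x$manifest$n_assessed, "\n")
  cat("chosen K:", x$manifest$chosen_k,
      "| mean max posterior:",
      sprintf("%.3f", x$manifest$mean_max_posterior), "\n")
  invisible(x)
}

#' Deterministic test cohorts
#'
#' Bundled configurations used across the test-suite: `tiny` (n = 12,
#' smoke tests), `small` (n = 120), `default` (n = 801, the study-scale
#' conditions). Hard-coded seeds make every call byte-identical.
#'
#' @param size `"tiny"`, `"small"`, or `"default"`.
#' @param noiseless strip measurement noise and subject-level variation
#'   (useful for exactness tests).
#' @param single_class collapse to one latent class.
#' @return an [sim_config()].
#' @export
make_fixtures <- function(size = c("tiny", "small", "default"),
                          noiseless = FALSE, single_class = FALSE) {
  size <- match.arg(size)
  n <- c(tiny = 12L, small = 120L, default = 801L)[[size]]
  seed <- c(tiny = 101L, small = 202L, default = 303L)[[size]]
  args <- list(n_subjects = n, seed = seed)
  if (noiseless) {
    args$noise_cv <- c(bpd = 0, ac = 0, fl = 0)
    args$size_sd <- 0
    args$random_intercept_sd <- 0
    args$random_slope_sd <- 0
    args$resid_sd <- 0
    args$birthweight_noise_sd <- 0
    args$visit_jitter <- 0
  }
  if (single_class) {
    args$class_proportions <- 1
    args$class_archetypes <- default_archetypes()[2, , drop = FALSE]
    args$delivery_mean <- 39.3
    args$delivery_sd <- 1.2
  }
  do.call(sim_config, args)
}
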