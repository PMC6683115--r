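#' Configuration of the cohort inclusion funnel
#'
#' Boundary conventions for the eligibility rules. Ages and delivery weeks
#' are boundary-inclusive (`>=`); the visit-gap rule is strict (`< 5`
#' weeks); the EFW/birthweight consistency rule only applies when the last
#' scan lies within `efw_window_weeks` of delivery.
#'
#' @param age_min minimum maternal age in years (inclusive).
#' @param ga_delivery_min minimum gestational age at delivery in weeks
#'   (inclusive).
#' @param first_scan_before latest permitted week of the earliest scan
#'   (strict: a scan before 22 weeks is required by default).
#' @param max_gap_weeks largest allowed interval between consecutive scans
#'   (strict upper bound).
#' @param efw_discrepancy maximum allowed relative discrepancy between the
#'   last EFW and the birthweight.
#' @param efw_window_weeks the discrepancy rule applies only when the last
#'   scan is within this many weeks of delivery.
#' @return list of class `fv_funnel_config`.
#' @export
funnel_config <- function(age_min = 20, ga_delivery_min = 28,
                          first_scan_before = 22, max_gap_weeks = 5,
                          efw_discrepancy = 0.20, efw_window_weeks = 1) {
  structure(list(age_min = age_min, ga_delivery_min = ga_delivery_min,
                 first_scan_before = first_scan_before,
                 max_gap_weeks = max_gap_weeks,
                 efw_discrepancy = efw_discrepancy,
                 efw_window_weeks = efw_window_weeks),
            class = "fv_funnel_config")
}

.need_fields <- function(df, fields, criterion) {
  miss <- setdiff(fields, names(df))
  if (length(miss))
    stop("criterion '", criterion, "' requires field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Apply the cohort eligibility funnel
#'
#' Applies, in order: (1) ethnically Japanese singleton pregnancies;
#' (2) maternal age of at least `age_min`; (3) delivery at or after
#' `ga_delivery_min` weeks; (4) at least one scan before week
#' `first_scan_before`; (5) longest interval between consecutive scans
#' strictly below `max_gap_weeks`; (6) one delivery per woman (the lowest
#' `delivery_index` is kept); (7) when the last scan is within
#' `efw_window_weeks` of delivery, the relative discrepancy between the
#' last EFW and the birthweight must not exceed `efw_discrepancy`.
#'
#' @param visits,maternal,neonatal the three cohort tables sharing
#'   `subject_id`. `maternal` may carry a `woman_id` column grouping
#'   deliveries of the same woman; without it each subject is taken as a
#'   distinct woman.
#' @param config a [funnel_config()].
#' @return list of class `fv_funnel` with elements `ids` (eligible
#'   subjects), `report` (data.frame `criterion`, `n_remaining`), and the
#'   three filtered tables.
#' @export
apply_inclusion_criteria <- function(visits, maternal, neonatal,
                                     config = funnel_config()) {
  .need_fields(visits, c("subject_id", "ga_weeks"), "visit structure")
  .need_fields(maternal, "subject_id", "maternal structure")
  .need_fields(neonatal, "subject_id", "neonatal structure")
  ids <- unique(maternal$subject_id)
  report <- data.frame(criterion = "assessed", n_remaining = length(ids),
                       stringsAsFactors = FALSE)
  keep_step <- function(ids, label, keep_ids) {
    ids <- ids[ids %in% keep_ids]
    report <<- rbind(report, data.frame(criterion = label,
                                        n_remaining = length(ids)))
    ids
  }

  # 1: Japanese singleton
  .need_fields(maternal, c("ethnicity_japanese", "singleton"),
               "japanese_singleton")
  ok <- maternal$subject_id[maternal$ethnicity_japanese & maternal$singleton]
  ids <- keep_step(ids, "japanese_singleton", ok)

  # 2: maternal age
  .need_fields(maternal, "age_years", "maternal_age")
  ok <- maternal$subject_id[maternal$age_years >= config$age_min]
  ids <- keep_step(ids, "maternal_age", ok)

  # 3: gestational age at delivery
  .need_fields(neonatal, "ga_delivery_weeks", "ga_delivery")
  ok <- neonatal$subject_id[neonatal$ga_delivery_weeks >= config$ga_delivery_min]
  ids <- keep_step(ids, "ga_delivery", ok)

  # 4: early sonogram
  first_scan <- tapply(visits$ga_weeks, visits$subject_id, min)
  ok <- names(first_scan)[first_scan < config$first_scan_before]
  ids <- keep_step(ids, "scan_before_22wk", ok)

  # 5: visit gaps
  gaps <- tapply(visits$ga_weeks, visits$subject_id, function(g) {
    g <- sort(g)
    if (length(g) < 2L) 0 else max(diff(g))
  })
  ok <- names(gaps)[gaps < config$max_gap_weeks]
  ids <- keep_step(ids, "max_scan_gap", ok)

  # 6: one delivery per woman
  if (is.null(maternal$woman_id)) {
    ok <- maternal$subject_id
  } else {
    .need_fields(maternal, "delivery_index", "one_delivery_per_woman")
    m <- maternal[maternal$subject_id %in% ids, , drop = FALSE]
    first_idx <- tapply(m$delivery_index, m$woman_id, min)
    ok <- m$subject_id[m$delivery_index == first_idx[as.character(m$woman_id)]]
  }
  ids <- keep_step(ids, "one_delivery_per_woman", ok)

  # 7: EFW vs birthweight consistency
  .need_fields(neonatal, c("ga_delivery_weeks", "birthweight_g"),
               "efw_consistency")
  v <- ensure_efw(visits)
  last_row <- do.call(rbind, lapply(split(v, v$subject_id), function(d) {
    d[which.max(d$ga_weeks), c("subject_id", "ga_weeks", "efw_g")]
  }))
  nn <- neonatal[match(last_row$subject_id, neonatal$subject_id), ]
  applies <- (nn$ga_delivery_weeks - last_row$ga_weeks) < config$efw_window_weeks
  rel <- abs(last_row$efw_g - nn$birthweight_g) / nn$birthweight_g
  ok <- last_row$subject_id[!applies | rel <= config$efw_discrepancy]
  ids <- keep_step(ids, "efw_consistency", ok)

  structure(list(
    ids = ids,
    report = report,
    visits = visits[visits$subject_id %in% ids, , drop = FALSE],
    maternal = maternal[maternal$subject_id %in% ids, , drop = FALSE],
    neonatal = neonatal[neonatal$subject_id %in% ids, , drop = FALSE]),
    class = "fv_funnel")
}

#' @export
print.fv_funnel <- function(x, ...) {
  cat("Inclusion funnel:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a funnel report as a two-column delimited table
#' @param funnel an `fv_funnel`.
#' @param path output file path.
#' @export
write_funnel_report <- function(funnel, path) {
  utils::write.csv(funnel$report, path, row.names = FALSE)
  invisible(path)
}
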