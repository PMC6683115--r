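#' Estimated fetal weight from standard biometry
#'
#' Computes the estimated fetal weight (EFW) from biparietal diameter,
#' abdominal circumference and femur length using the formula of the Japan
#' Society of Ultrasonics in Medicine:
#' \deqn{EFW[g] = 1.07\,BPD^3 + 0.3\,AC^2\,FL}
#' with all lengths in centimetres.
#'
#' @param bpd_cm biparietal diameter (cm). Vectorised.
#' @param ac_cm abdominal circumference (cm).
#' @param fl_cm femur length (cm).
#' @return Estimated fetal weight in grams.
#' @examples
#' compute_efw(9.0, 30.0, 7.0)  # 2670.03
#' @export
compute_efw <- function(bpd_cm, ac_cm, fl_cm) {
  for (nm in c("bpd_cm", "ac_cm", "fl_cm")) {
    v <- get(nm)
    if (any(!is.na(v) & v < 0))
      stop("negative value in '", nm, "'", call. = FALSE)
  }
  1.07 * bpd_cm^3 + 0.3 * ac_cm^2 * fl_cm
}

#' Gestational weight gain relative to pre-pregnancy weight
#'
#' The weight gain at each week is the maternal weight measured at that week
#' minus the pre-pregnancy weight. Weeks without a weight measurement are
#' simply absent from the result; nothing is imputed.
#'
#' @param visit_weights data.frame with columns `week` and `weight_kg`
#'   (rows with missing weight are dropped), or a named numeric vector with
#'   weeks as names.
#' @param prepreg_weight_kg pre-pregnancy weight (kg), must be positive.
#' @return data.frame with columns `week` and `gain_kg`.
#' @export
weekly_weight_gain <- function(visit_weights, prepreg_weight_kg) {
  stopifnot(is.numeric(prepreg_weight_kg), length(prepreg_weight_kg) == 1L,
            prepreg_weight_kg > 0)
  if (is.numeric(visit_weights)) {
    visit_weights <- data.frame(
      week = as.numeric(names(visit_weights)),
      weight_kg = as.numeric(visit_weights))
  }
  if (nrow(visit_weights) == 0L)
    return(data.frame(week = numeric(0), gain_kg = numeric(0)))
  keep <- !is.na(visit_weights$weight_kg)
  vw <- visit_weights[keep, , drop = FALSE]
  out <- data.frame(week = vw$week, gain_kg = vw$weight_kg - prepreg_weight_kg)
  out[order(out$week), , drop = FALSE]
}

# Fill efw_g where missing from BPD/AC/FL; optionally flag recorded values
# that disagree with the formula by more than `tol_g` grams.
#' Ensure every visit carries an EFW value
#'
#' Recorded EFW values are trusted when present; missing ones are recomputed
#' from BPD/AC/FL with [compute_efw()]. With `validate = TRUE`, recorded
#' values differing from the recomputed ones by more than `tol_g` grams are
#' reported via a warning (the recorded value is still kept).
#'
#' @param visits visits data.frame (columns `bpd_cm`, `ac_cm`, `fl_cm`,
#'   optionally `efw_g`).
#' @param validate flag recorded-vs-recomputed discrepancies.
#' @param tol_g discrepancy tolerance in grams.
#' @return `visits` with a complete `efw_g` column.
#' @export
ensure_efw <- function(visits, validate = FALSE, tol_g = 1) {
  if (is.null(visits$efw_g)) visits$efw_g <- NA_real_
  recomputed <- compute_efw(visits$bpd_cm, visits$ac_cm, visits$fl_cm)
  if (validate) {
    bad <- !is.na(visits$efw_g) & abs(visits$efw_g - recomputed) > tol_g
    if (any(bad))
      warning(sum(bad), " visit(s) with recorded EFW differing from the ",
              "formula by more than ", tol_g, " g", call. = FALSE)
  }
  miss <- is.na(visits$efw_g)
  visits$efw_g[miss] <- recomputed[miss]
  visits
}
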