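#' Fit a smoothing spline to one subject's log-scale biometry
#'
#' Fits a penalized cubic regression spline to log-transformed measurements
#' of one parameter over gestational age, the standard generalized-additive
#' smoother for sparse longitudinal biometry. The basis dimension is
#' `min(n_obs - 1, 10)` and the smoothing parameter is chosen by
#' generalized cross-validation, which keeps the fit deterministic.
#'
#' @param ga_weeks decimal gestational ages of the observations.
#' @param values strictly positive natural-scale measurements.
#' @param method mgcv smoothing-parameter criterion (default `"GCV.Cp"`;
#'   `"REML"` available).
#' @return list of class `fv_spline_fit`: `predict_log(ga)` evaluates the
#'   fitted log-scale curve; `edf` the effective degrees of freedom;
#'   `max_abs_resid` the largest absolute log-scale residual at the
#'   observation times; `last_obs_week`, `first_obs_week`, `k` the basis
#'   dimension.
#' @export
fit_subject_spline <- function(ga_weeks, values, method = "GCV.Cp") {
  ok <- !is.na(values) & !is.na(ga_weeks)
  ga_weeks <- ga_weeks[ok]; values <- values[ok]
  if (length(ga_weeks) < 4L)
    stop("un-fittable subject: fewer than 4 observations", call. = FALSE)
  if (any(values <= 0))
    stop("non-positive measurement on the log scale", call. = FALSE)
  ord <- order(ga_weeks)
  ga_weeks <- ga_weeks[ord]; values <- values[ord]
  if (any(diff(ga_weeks) == 0))
    stop("duplicate gestational ages for one subject", call. = FALSE)
  k <- min(length(ga_weeks) - 1L, 10L)
  k <- max(k, 3L)
  # cubic B-spline basis (spans all cubics); natural-spline fallback when
  # too few visits support a B-spline basis
  bs <- if (k >= 5L) "bs" else "cr"
  dat <- data.frame(ga = ga_weeks, ly = log(values))
  fit <- mgcv::gam(ly ~ s(ga, k = k, bs = bs), data = dat, method = method)
  pred <- function(ga) as.numeric(mgcv::predict.gam(fit, data.frame(ga = ga)))
  structure(list(
    predict_log = pred,
    edf = sum(fit$edf),              # includes the intercept
    max_abs_resid = max(abs(stats::residuals(fit))),
    first_obs_week = ga_weeks[1L],
    last_obs_week = ga_weeks[length(ga_weeks)],
    k = k), class = "fv_spline_fit")
}

#' Evaluate a subject spline on the integer-week grid
#'
#' Exponentiates the log-scale fit at integer weeks. Weeks more than
#' `max_extrapolation` weeks beyond the last observation are returned as
#' `NA` rather than extrapolated, to keep late-gestation estimates stable
#' for subjects delivering early.
#'
#' @param fit an `fv_spline_fit`.
#' @param weeks integer grid (default 19:38).
#' @param max_extrapolation extrapolation cap in weeks beyond the last
#'   observation.
#' @return data.frame with `week`, `log_value`, `value` (`NA` beyond the
#'   cap).
#' @export
weekly_values <- function(fit, weeks = 19:38, max_extrapolation = 3) {
  stopifnot(inherits(fit, "fv_spline_fit"))
  usable <- weeks <= fit$last_obs_week + max_extrapolation + 1e-9
  if (!any(usable))
    stop("grid entirely beyond the observation span", call. = FALSE)
  lv <- rep(NA_real_, length(weeks))
  lv[usable] <- fit$predict_log(weeks[usable])
  data.frame(week = weeks, log_value = lv, value = exp(lv))
}

#' Week-over-week growth velocity
#'
#' The velocity at week \eqn{w} is the backward difference
#' \eqn{v_w = y_w - y_{w-1}} on the natural scale, defined for every week
#' whose predecessor is also present; a 19--38 week value grid yields
#' velocities on weeks 20--38. Missing values propagate.
#'
#' @param weekly data.frame with `week` and `value` (from
#'   [weekly_values()]), or a numeric vector of values at consecutive
#'   integer weeks named by week.
#' @return data.frame with `week` and `velocity`.
#' @export
weekly_velocity <- function(weekly) {
  if (is.numeric(weekly))
    weekly <- data.frame(week = as.numeric(names(weekly)), value = weekly)
  weekly <- weekly[order(weekly$week), , drop = FALSE]
  if (nrow(weekly) < 2L)
    return(data.frame(week = numeric(0), velocity = numeric(0)))
  w <- weekly$week; y <- weekly$value
  consec <- diff(w) == 1
  data.frame(week = w[-1L][consec], velocity = diff(y)[consec])
}

#' Interpolate a cohort's visits to weekly values and velocities
#'
#' Runs [fit_subject_spline()] + [weekly_values()] + [weekly_velocity()]
#' for each subject and each requested parameter. Subjects that cannot be
#' fitted (fewer than 4 visits, or grid entirely beyond their span) are
#' dropped with a logged reason.
#'
#' @param visits visits table (`subject_id`, `ga_weeks`, `bpd_cm`, `ac_cm`,
#'   `fl_cm`, optional `efw_g`).
#' @param parameters subset of `c("EFW", "BPD", "AC", "FL")`.
#' @param weeks integer grid.
#' @param max_extrapolation see [weekly_values()].
#' @param method see [fit_subject_spline()].
#' @return list of class `fv_weekly`: `grid` (long data.frame `subject_id`,
#'   `parameter`, `week`, `value`, `log_value`, `velocity`), `diagnostics`
#'   (per subject x parameter: edf, basis size, max abs residual),
#'   `excluded` (subject, reason).
#' @export
cohort_weekly <- function(visits, parameters = c("EFW", "BPD", "AC", "FL"),
                          weeks = 19:38, max_extrapolation = 3,
                          method = "GCV.Cp") {
  parameters <- match.arg(parameters, c("EFW", "BPD", "AC", "FL"),
                          several.ok = TRUE)
  if ("EFW" %in% parameters) visits <- ensure_efw(visits)
  col_of <- c(EFW = "efw_g", BPD = "bpd_cm", AC = "ac_cm", FL = "fl_cm")
  rows <- list(); diags <- list(); excl <- list()
  for (sid in unique(visits$subject_id)) {
    sv <- visits[visits$subject_id == sid, , drop = FALSE]
    for (p in parameters) {
      res <- tryCatch({
        fit <- fit_subject_spline(sv$ga_weeks, sv[[col_of[[p]]]],
                                  method = method)
        wv <- weekly_values(fit, weeks, max_extrapolation)
        vel <- weekly_velocity(wv)
        wv$velocity <- vel$velocity[match(wv$week, vel$week)]
        wv$subject_id <- sid; wv$parameter <- p
        diags[[length(diags) + 1L]] <- data.frame(
          subject_id = sid, parameter = p, edf = fit$edf, k = fit$k,
          max_abs_resid = fit$max_abs_resid,
          last_obs_week = fit$last_obs_week)
        wv
      }, error = function(e) {
        excl[[length(excl) + 1L]] <<- data.frame(
          subject_id = sid, parameter = p, reason = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  grid <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), parameter = character(0),
               week = integer(0), value = numeric(0),
               log_value = numeric(0), velocity = numeric(0))
  structure(list(
    grid = grid[, c("subject_id", "parameter", "week", "value",
                    "log_value", "velocity")],
    diagnostics = if (length(diags)) do.call(rbind, diags) else NULL,
    excluded = if (length(excl)) do.call(rbind, excl) else NULL,
    weeks = weeks), class = "fv_weekly")
}

#' Cohort z-score panel for weekly sizes and velocities
#'
#' Weekly means and standard deviations (sample SD, \eqn{n-1} denominator)
#' per parameter, computed over the subjects with a value at that week,
#' separately for sizes and velocities. These are the cohort-internal
#' reference against which individual trajectories are standardized.
#'
#' @param grid the long grid from [cohort_weekly()].
#' @return data.frame of class `fv_zpanel` (`parameter`, `week`, `kind`,
#'   `mean`, `sd`, `n`).
#' @export
build_zscore_panel <- function(grid) {
  panel <- list()
  for (kind in c("value", "velocity")) {
    x <- grid[!is.na(grid[[kind]]), c("parameter", "week", kind)]
    if (!nrow(x)) next
    agg <- stats::aggregate(x[[kind]],
                            by = list(parameter = x$parameter, week = x$week),
                            FUN = function(v) c(mean(v), stats::sd(v),
                                                length(v)))
    panel[[kind]] <- data.frame(parameter = agg$parameter, week = agg$week,
                                kind = kind, mean = agg$x[, 1],
                                sd = agg$x[, 2], n = agg$x[, 3])
  }
  panel <- do.call(rbind, panel)
  bad <- panel$n < 2
  if (any(bad))
    stop("z-score panel cell with fewer than 2 subjects: ",
         paste(panel$parameter[bad], panel$week[bad], panel$kind[bad],
               collapse = "; "), call. = FALSE)
  degen <- panel$sd == 0
  if (any(degen))
    stop("degenerate cohort: zero SD at ",
         paste(panel$parameter[degen], panel$week[degen], panel$kind[degen],
               collapse = "; "), call. = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("fv_zpanel", "data.frame")
  panel
}

#' Standardize a weekly grid against a z-score panel
#'
#' @param grid long grid from [cohort_weekly()] (possibly for new
#'   subjects).
#' @param panel an `fv_zpanel`, typically from [build_zscore_panel()].
#' @return `grid` with added `z_value` and `z_velocity` columns.
#' @export
apply_zscore_panel <- function(grid, panel) {
  key <- function(p, w, k) paste(p, w, k, sep = "\r")
  pm <- stats::setNames(panel$mean, key(panel$parameter, panel$week, panel$kind))
  ps <- stats::setNames(panel$sd, key(panel$parameter, panel$week, panel$kind))
  kv <- key(grid$parameter, grid$week, "value")
  kk <- key(grid$parameter, grid$week, "velocity")
  grid$z_value <- (grid$value - pm[kv]) / ps[kv]
  grid$z_velocity <- (grid$velocity - pm[kk]) / ps[kk]
  rownames(grid) <- NULL
  grid
}
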