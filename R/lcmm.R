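#' Specification of the latent-class linear mixed model
#'
#' The model for a weekly outcome series \eqn{y_i} (velocity by default) is
#' a finite mixture of linear mixed models: conditional on latent class
#' \eqn{g}, \eqn{y_i = X_i \beta_g + Z_i b_i + e_i} with
#' \eqn{b_i \sim N(0, D)}, \eqn{e_i \sim N(0, \sigma^2 I)}; class
#' membership has intercept-only multinomial logits (equivalently a simplex
#' of weights \eqn{\pi}). \eqn{X_i} is an orthogonalized polynomial basis
#' of degree `degree` in gestational week centered at `center`; \eqn{Z_i}
#' is subject intercept + centered week (or slope only). \eqn{D} and
#' \eqn{\sigma^2} are shared across classes.
#'
#' @param n_classes number of latent classes K (>= 1).
#' @param degree fixed-effect polynomial degree (default 4, quartic).
#' @param random `"intercept+slope"` (default) or `"slope"`.
#' @param center centering week for the polynomial time scale (default
#'   28.5, the midpoint of the 19--38 analysis window).
#' @param order_week week at which fitted mean outcomes are compared to
#'   canonically order classes (descending; default 31, where the
#'   late-deceleration and steady shapes separate).
#' @return list of class `fv_lcmm_spec`.
#' @export
lcmm_spec <- function(n_classes = 3, degree = 4,
                      random = c("intercept+slope", "slope"),
                      center = 28.5, order_week = 31) {
  stopifnot(n_classes >= 1, degree >= 0)
  random <- match.arg(random)
  structure(list(n_classes = as.integer(n_classes),
                 degree = as.integer(degree), random = random,
                 center = center, order_week = order_week),
            class = "fv_lcmm_spec")
}

# Build the internal data object: per-pattern grouping of subjects with
# identical observed-week sets, with shared design matrices.
.lcmm_data <- function(outcome_long, spec, min_obs = 3L) {
  stopifnot(all(c("subject_id", "week", "y") %in% names(outcome_long)))
  d <- outcome_long[!is.na(outcome_long$y), , drop = FALSE]
  grid <- sort(unique(d$week))
  if (length(grid) <= spec$degree)
    stop("polynomial degree ", spec$degree, " needs more than ",
         spec$degree, " distinct weeks", call. = FALSE)
  u <- grid - spec$center
  P <- spec$degree + 1L
  B <- cbind(1, stats::poly(u, degree = spec$degree))
  colnames(B) <- paste0("p", 0:spec$degree)
  Z <- if (spec$random == "intercept+slope") cbind(1, u) else cbind(u)
  sids <- unique(d$subject_id)
  obs <- split(d[, c("week", "y")], factor(d$subject_id, levels = sids))
  keep <- vapply(obs, nrow, 1L) >= min_obs
  excluded <- sids[!keep]
  sids <- sids[keep]; obs <- obs[keep]
  if (!length(sids)) stop("no subject has enough observed weeks", call. = FALSE)
  idx <- lapply(obs, function(o) match(sort(o$week), grid))
  yvec <- lapply(seq_along(obs), function(i) {
    o <- obs[[i]]; o$y[order(o$week)]
  })
  pat_key <- vapply(idx, paste, "", collapse = ",")
  patterns <- list()
  for (key in unique(pat_key)) {
    members <- which(pat_key == key)
    rows <- idx[[members[1L]]]
    patterns[[key]] <- list(
      rows = rows,
      m = length(rows),
      members = members,
      X = B[rows, , drop = FALSE],
      Z = Z[rows, , drop = FALSE],
      Y = do.call(rbind, yvec[members]))
  }
  list(subject_id = sids, N = length(sids), patterns = patterns,
       grid = grid, B = B, Z = Z, P = P, q = ncol(Z),
       n_obs_total = sum(vapply(patterns, function(p) p$m * nrow(p$Y), 1)),
       excluded = excluded)
}

# Per-subject log joint density matrix log(pi_g) + log N(y_i; X beta_g, V_i)
# plus the per-pattern factorizations, reused by the M-step.
.lcmm_estep <- function(dat, beta, pi, D, sigma2) {
  K <- length(pi)
  logdens <- matrix(NA_real_, dat$N, K)
  fact <- list()
  for (key in names(dat$patterns)) {
    p <- dat$patterns[[key]]
    V <- p$Z %*% D %*% t(p$Z) + diag(sigma2, p$m)
    R <- chol(V)
    logdet <- 2 * sum(log(diag(R)))
    XB <- p$X %*% beta                       # m x K
    for (g in seq_len(K)) {
      Rm <- p$Y - matrix(XB[, g], nrow(p$Y), p$m, byrow = TRUE)
      W1 <- backsolve(R, t(Rm), transpose = TRUE)
      q <- colSums(W1^2)
      logdens[p$members, g] <- -0.5 * (p$m * log(2 * pi_const) + logdet + q)
    }
    fact[[key]] <- R
  }
  lj <- sweep(logdens, 2, log(pi), "+")
  mx <- apply(lj, 1, max)
  w <- exp(lj - mx)
  tot <- rowSums(w)
  list(loglik = sum(mx + log(tot)), W = w / tot, fact = fact)
}

pi_const <- base::pi

#' Marginal log-likelihood of the latent-class linear mixed model
#'
#' Evaluates \eqn{\sum_i \log \sum_g \pi_g N(y_i; X_i\beta_g,
#' Z_i D Z_i' + \sigma^2 I)} via Cholesky factorization per observation
#' pattern, with the class sum in log space.
#'
#' @param outcome_long data.frame `subject_id`, `week`, `y`.
#' @param spec an [lcmm_spec()].
#' @param beta (degree+1) x K matrix of class fixed effects on the
#'   orthogonalized basis.
#' @param pi class weights on the simplex.
#' @param D random-effect covariance (q x q, PSD).
#' @param sigma2 residual variance (> 0).
#' @return scalar log-likelihood.
#' @export
lcmm_loglik <- function(outcome_long, spec, beta, pi, D, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  D <- (D + t(D)) / 2
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("D must be positive semidefinite", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0))
    stop("pi must lie on the simplex", call. = FALSE)
  dat <- .lcmm_data(outcome_long, spec)
  .lcmm_estep(dat, beta, pi, D, sigma2)$loglik
}

# Weighted GLS update of class means given variance components and
# posterior weights W (N x K). Returns P x K matrix.
.lcmm_update_beta <- function(dat, W, D, sigma2, fact) {
  K <- ncol(W); P <- dat$P
  beta <- matrix(NA_real_, P, K)
  A <- array(0, c(P, P, K)); rhs <- matrix(0, P, K)
  for (key in names(dat$patterns)) {
    p <- dat$patterns[[key]]
    Vinv <- chol2inv(fact[[key]])
    XtVi <- t(p$X) %*% Vinv                  # P x m
    XtViX <- XtVi %*% p$X
    for (g in seq_len(K)) {
      wg <- W[p$members, g]
      A[, , g] <- A[, , g] + sum(wg) * XtViX
      rhs[, g] <- rhs[, g] + XtVi %*% crossprod(p$Y, wg)
    }
  }
  for (g in seq_len(K)) beta[, g] <- solve(A[, , g], rhs[, g])
  beta
}

# Closed-form EM updates of D and sigma2 given beta and posterior weights,
# using E[b_i | y_i, g] and its conditional covariance.
.lcmm_update_varcomp <- function(dat, W, beta, D, sigma2, fact) {
  K <- ncol(W); q <- dat$q
  Dacc <- matrix(0, q, q); s_num <- 0; n_obs <- 0
  for (key in names(dat$patterns)) {
    p <- dat$patterns[[key]]
    Vinv <- chol2inv(fact[[key]])
    A <- D %*% t(p$Z) %*% Vinv               # q x m
    Cb <- D - A %*% p$Z %*% D                # cond. covariance of b
    trVinv <- sum(diag(Vinv))
    XB <- p$X %*% beta
    n_obs <- n_obs + p$m * nrow(p$Y)
    for (g in seq_len(K)) {
      wg <- W[p$members, g]
      Rm <- p$Y - matrix(XB[, g], nrow(p$Y), p$m, byrow = TRUE)
      bhat <- Rm %*% t(A)                    # n_p x q
      Dacc <- Dacc + crossprod(bhat, bhat * wg) + sum(wg) * Cb
      U2 <- Rm %*% Vinv
      q2 <- rowSums(U2^2)
      s_num <- s_num + sum(wg * (sigma2^2 * q2 + sigma2 * p$m -
                                   sigma2^2 * trVinv))
    }
  }
  D_new <- (Dacc + t(Dacc)) / (2 * dat$N)
  list(D = D_new, sigma2 = max(s_num / n_obs, 1e-12))
}

# Per-subject least-squares polynomial coefficients used to seed k-means.
.subject_coefs <- function(dat) {
  co <- matrix(0, dat$N, dat$P)
  for (key in names(dat$patterns)) {
    p <- dat$patterns[[key]]
    XtX <- crossprod(p$X) + diag(1e-6, dat$P)
    co[p$members, ] <- t(solve(XtX, t(p$Y %*% p$X)))
  }
  co
}

.init_params <- function(dat, K, labels) {
  P <- dat$P; q <- dat$q
  beta <- matrix(0, P, K)
  resid_all <- numeric(0)
  bmat <- NULL
  for (g in seq_len(K)) {
    members <- which(labels == g)
    XtX <- matrix(0, P, P); rhs <- numeric(P)
    for (key in names(dat$patterns)) {
      p <- dat$patterns[[key]]
      sel <- p$members %in% members
      if (!any(sel)) next
      XtX <- XtX + sum(sel) * crossprod(p$X)
      rhs <- rhs + crossprod(p$X, colSums(p$Y[sel, , drop = FALSE]))
    }
    beta[, g] <- solve(XtX + diag(1e-8, P), rhs)
  }
  # crude random-effect seeds from per-subject residual regressions
  for (key in names(dat$patterns)) {
    p <- dat$patterns[[key]]
    XB <- p$X %*% beta
    ZtZ <- crossprod(p$Z) + diag(1e-8, q)
    for (i in seq_len(nrow(p$Y))) {
      g <- labels[p$members[i]]
      r <- p$Y[i, ] - XB[, g]
      b <- solve(ZtZ, crossprod(p$Z, r))
      bmat <- rbind(bmat, as.numeric(b))
      resid_all <- c(resid_all, r - p$Z %*% b)
    }
  }
  D0 <- stats::cov(bmat)
  D0 <- (D0 + t(D0)) / 2 + diag(1e-8, q)
  s0 <- max(stats::var(resid_all), 1e-8)
  pi0 <- as.numeric(table(factor(labels, levels = seq_len(K)))) / length(labels)
  pi0 <- pmax(pi0, 0.02); pi0 <- pi0 / sum(pi0)
  list(beta = beta, pi = pi0, D = D0, sigma2 = s0)
}

.run_em <- function(dat, K, init, tol, max_iter) {
  beta <- init$beta; pi <- init$pi; D <- init$D; sigma2 <- init$sigma2
  trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (it in seq_len(max_iter)) {
    es <- .lcmm_estep(dat, beta, pi, D, sigma2)
    trace <- c(trace, es$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
        tol * (1 + abs(trace[it]))) { converged <- TRUE; break }
    beta <- .lcmm_update_beta(dat, es$W, D, sigma2, es$fact)
    es2 <- .lcmm_estep(dat, beta, pi, D, sigma2)
    vc <- .lcmm_update_varcomp(dat, es2$W, beta, D, sigma2, es2$fact)
    pi <- pmax(colMeans(es2$W), 1e-12); pi <- pi / sum(pi)
    D <- vc$D; sigma2 <- vc$sigma2
  }
  list(beta = beta, pi = pi, D = D, sigma2 = sigma2,
       loglik = trace[length(trace)], trace = trace,
       posterior = es$W, converged = converged, n_iter = length(trace))
}

#' Fit the latent-class linear mixed model by multi-start EM
#'
#' Estimation alternates an E-step over class membership (random effects
#' integrated analytically) with a weighted generalized-least-squares
#' update of the class mean curves, and an E-step over (class, random
#' effects) with closed-form updates of the mixture weights and variance
#' components. Both half-steps maximize the corresponding expected
#' complete-data log-likelihood, so the observed-data log-likelihood is
#' non-decreasing across iterations. Starts are seeded from k-means
#' clustering of per-subject least-squares polynomial coefficients, with
#' random relabelling perturbations for subsequent starts; the best
#' converged start is returned. Classes are canonically reordered by
#' descending fitted mean outcome at `spec$order_week`.
#'
#' @param outcome_long data.frame `subject_id`, `week`, `y` (one row per
#'   subject-week; `NA` rows are dropped; subjects need >= 3 weeks).
#' @param spec an [lcmm_spec()].
#' @param n_starts number of EM starts (default 20).
#' @param seed integer seed driving initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @return object of class `fv_lcmm`: `beta`, `pi`, `D`, `sigma2`,
#'   `loglik`, `n_params`, `bic`, `posterior` (N x K), `assignment`,
#'   `class_curves` (week, class, mean), `loglik_trace`, `converged`,
#'   `n_iter`, `spec`, `grid`, `subject_id`, `n_subjects`, `excluded`,
#'   `start_logliks`, `order_permutation`.
#' @export
fit_lcmm <- function(outcome_long, spec = lcmm_spec(), n_starts = 20,
                     seed = 1, tol = 1e-8, max_iter = 500) {
  K <- spec$n_classes
  dat <- .lcmm_data(outcome_long, spec)
  if (K > dat$N) stop("more classes than subjects", call. = FALSE)
  co <- .subject_coefs(dat)
  co_s <- scale(co)
  co_s[, apply(co, 2, stats::sd) == 0] <- 0
  best <- NULL; start_lls <- rep(NA_real_, n_starts)
  set.seed(seed %% .Machine$integer.max)
  for (s in seq_len(n_starts)) {
    labels <- if (K == 1L) rep(1L, dat$N) else
      tryCatch(stats::kmeans(co_s, centers = K, nstart = 2)$cluster,
               error = function(e) sample.int(K, dat$N, replace = TRUE))
    if (s > 1 && K > 1) {  # perturb: relabel a random 20% of subjects
      flip <- sample.int(dat$N, max(1L, round(0.2 * dat$N)))
      labels[flip] <- sample.int(K, length(flip), replace = TRUE)
    }
    if (length(unique(labels)) < K) labels[sample.int(dat$N, K)] <- seq_len(K)
    res <- tryCatch(
      .run_em(dat, K, .init_params(dat, K, labels), tol, max_iter),
      error = function(e) NULL)
    if (is.null(res)) next
    start_lls[s] <- res$loglik
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop("all EM starts failed", call. = FALSE)

  # canonical ordering by fitted mean outcome at order_week, descending
  ow <- dat$grid[which.min(abs(dat$grid - spec$order_week))]
  row_ow <- dat$B[match(ow, dat$grid), , drop = FALSE]
  v_ow <- as.numeric(row_ow %*% best$beta)
  perm <- order(v_ow, decreasing = TRUE)
  beta <- best$beta[, perm, drop = FALSE]
  pi <- best$pi[perm]
  posterior <- best$posterior[, perm, drop = FALSE]
  rownames(posterior) <- dat$subject_id
  assignment <- max.col(posterior, ties.method = "first")

  P <- dat$P; q <- dat$q
  n_params <- K * P + (K - 1) + q * (q + 1) / 2 + 1
  bic <- -2 * best$loglik + n_params * log(dat$N)
  curves <- data.frame(
    week = rep(dat$grid, K),
    class = rep(seq_len(K), each = length(dat$grid)),
    mean = as.numeric(dat$B %*% beta))
  structure(list(
    beta = beta, pi = pi, D = best$D, sigma2 = best$sigma2,
    loglik = best$loglik, n_params = n_params, bic = bic,
    posterior = posterior, assignment = assignment,
    class_curves = curves, loglik_trace = best$trace,
    converged = best$converged, n_iter = best$n_iter,
    spec = spec, grid = dat$grid, subject_id = dat$subject_id,
    n_subjects = dat$N, excluded = dat$excluded,
    start_logliks = start_lls, order_permutation = perm),
    class = "fv_lcmm")
}

#' @export
print.fv_lcmm <- function(x, ...) {
  cat("Latent-class linear mixed model: K =", x$spec$n_classes,
      "| N =", x$n_subjects, "\n")
  cat("logLik:", format(x$loglik, digits = 10),
      " BIC:", format(x$bic, digits = 10),
      " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("class proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("sigma2:", format(x$sigma2, digits = 6), "\n")
  invisible(x)
}

#' Raw-scale polynomial coefficients of the fitted class mean curves
#'
#' Back-transforms the orthogonalized-basis coefficients to coefficients of
#' powers of centered week, exactly (the fitted curve is a polynomial of
#' the same degree).
#'
#' @param fit an `fv_lcmm`.
#' @return (degree+1) x K matrix; row j is the coefficient of
#'   `(week - center)^(j-1)`.
#' @export
raw_coefficients <- function(fit) {
  u <- fit$grid - fit$spec$center
  V <- outer(u, 0:fit$spec$degree, "^")
  B <- cbind(1, stats::poly(u, degree = fit$spec$degree))
  qr.solve(V, B %*% fit$beta)
}

#' Fit the latent-class model over a range of class counts
#'
#' Fits each K with shared settings and selects the fit with the lowest
#' BIC (\eqn{-2\log L + p \log N}).
#'
#' @inheritParams fit_lcmm
#' @param k_range candidate class counts (default 1:4).
#' @return list of class `fv_lcmm_selection`: `fits` (per K), `table`
#'   (K, loglik, n_params, bic, converged), `chosen_k`, `best` (the chosen
#'   fit).
#' @export
select_k <- function(outcome_long, spec = lcmm_spec(), k_range = 1:4,
                     n_starts = 20, seed = 1, tol = 1e-8, max_iter = 500) {
  stopifnot(length(k_range) >= 1)
  k_range <- as.integer(k_range)
  fits <- list()
  for (K in k_range) {
    sp <- spec; sp$n_classes <- as.integer(K)
    fits[[as.character(K)]] <- fit_lcmm(outcome_long, sp,
                                        n_starts = n_starts,
                                        seed = seed + K, tol = tol,
                                        max_iter = max_iter)
  }
  tab <- data.frame(
    k = k_range,
    loglik = vapply(fits, function(f) f$loglik, 1),
    n_params = vapply(fits, function(f) f$n_params, 1),
    bic = vapply(fits, function(f) f$bic, 1),
    converged = vapply(fits, function(f) f$converged, TRUE))
  chosen <- k_range[which.min(tab$bic)]
  structure(list(fits = fits, table = tab, chosen_k = chosen,
                 best = fits[[as.character(chosen)]]),
            class = "fv_lcmm_selection")
}

#' @export
print.fv_lcmm_selection <- function(x, ...) {
  cat("Class-count selection by BIC:\n")
  print(x$table, row.names = FALSE)
  cat("chosen K =", x$chosen_k, "\n")
  invisible(x)
}

#' Posterior classification diagnostics
#'
#' @param fit an `fv_lcmm`.
#' @return list of class `fv_posterior_report`: `class_table` (per class:
#'   n, proportion, mean posterior of that class among its members),
#'   `mean_max_posterior` (overall mean of each subject's maximum
#'   posterior), `entropy` (relative entropy-based classification quality,
#'   1 = perfect separation).
#' @export
posterior_report <- function(fit) {
  P <- fit$posterior
  K <- ncol(P)
  asn <- fit$assignment
  cls <- lapply(seq_len(K), function(g) P[asn == g, g])
  class_table <- data.frame(
    class = seq_len(K),
    n = vapply(cls, length, 1L),
    proportion = vapply(cls, length, 1L) / nrow(P),
    mean_posterior = vapply(cls, function(v) if (length(v)) mean(v) else NA_real_, 1))
  maxp <- P[cbind(seq_len(nrow(P)), asn)]
  ent <- -sum(P * log(pmax(P, 1e-300)))
  rel_entropy <- if (K == 1L) 1 else 1 - ent / (nrow(P) * log(K))
  structure(list(class_table = class_table,
                 mean_max_posterior = mean(maxp),
                 entropy = rel_entropy),
            class = "fv_posterior_report")
}

#' @export
print.fv_posterior_report <- function(x, ...) {
  print(x$class_table, row.names = FALSE)
  cat(sprintf("mean max posterior: %.4f | relative entropy: %.4f\n",
              x$mean_max_posterior, x$entropy))
  invisible(x)
}

#' Extract a long outcome series for the mixture model
#'
#' @param weekly an `fv_weekly` from [cohort_weekly()], or a long grid
#'   data.frame (e.g. from [apply_zscore_panel()]).
#' @param parameter biometry parameter.
#' @param outcome `"velocity"` (default), `"value"`, or their
#'   standardized forms `"z_velocity"` / `"z_value"` (grid must carry the
#'   z columns).
#' @return data.frame `subject_id`, `week`, `y`.
#' @export
outcome_long <- function(weekly, parameter = "EFW",
                         outcome = c("velocity", "value",
                                     "z_velocity", "z_value")) {
  outcome <- match.arg(outcome)
  grid <- if (inherits(weekly, "fv_weekly")) weekly$grid else weekly
  g <- grid[grid$parameter == parameter, , drop = FALSE]
  out <- data.frame(subject_id = g$subject_id, week = g$week,
                    y = g[[outcome]])
  out[!is.na(out$y), , drop = FALSE]
}
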