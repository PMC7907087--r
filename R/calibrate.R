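# Calibration of the sigmoid loss model: Levenberg-Marquardt least squares,
# goodness-of-fit statistics, observation-level prediction bounds and
# repeated random-split cross-validation.

#' Validate a table of measured medium-concentration ratios
#'
#' One row per observation of C(t)/C(0) for a chemical under a given cover,
#' medium volume and exposure time. Ratios must be non-negative; ratios
#' above 1.2 are treated as measurement artifacts and dropped with a
#' warning (a true ratio cannot exceed 1, but modest analytical overshoot
#' is tolerated). Exposure times must be positive.
#'
#' @param x data.frame with columns `name`, `ratio` and optionally `cover`,
#'   `medium_volume_ml`, `time_h`, `sd`, `n`, `source`.
#' @return `x` with all columns present, classed `ratio_records`.
#' @seealso [read_ratio_records()], [simulate_ratios()]
#' @export
as_ratio_records <- function(x) {
  if (!is.data.frame(x))
    stop("ratio records must be a data.frame", call. = FALSE)
  req <- setdiff(c("name", "ratio"), names(x))
  if (length(req))
    stop("ratio table lacks required column(s): ",
         paste(req, collapse = ", "), call. = FALSE)
  defaults <- list(cover = "custom", medium_volume_ml = NA_real_,
                   time_h = 24, sd = NA_real_, n = NA_integer_,
                   source = NA_character_)
  for (col in names(defaults))
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  x <- x[, c("name", "cover", "medium_volume_ml", "time_h", "ratio",
             "sd", "n", "source"), drop = FALSE]
  x$ratio <- as.numeric(x$ratio)
  if (any(!is.finite(x$ratio)) || any(x$ratio < 0))
    stop("ratios must be finite and >= 0", call. = FALSE)
  if (any(!is.na(x$time_h) & x$time_h <= 0))
    stop("exposure time must be > 0 h", call. = FALSE)
  implausible <- x$ratio > 1.2
  if (any(implausible)) {
    warning(sum(implausible), " ratio(s) > 1.2 rejected as implausible",
            call. = FALSE)
    x <- x[!implausible, , drop = FALSE]
  }
  class(x) <- c("ratio_records", "data.frame")
  x
}

# Merge ratio records with a chemical table (by name) and average replicate
# observations per chemical; returns one row per chemical with columns
# name, log_kow, log_hlc, ratio.
.calibration_frame <- function(data, chems = NULL,
                               average_replicates = TRUE) {
  df <- as.data.frame(data)
  if (!is.null(chems)) {
    chems <- as_chemicals(as.data.frame(chems))
    unknown <- setdiff(df$name, chems$name)
    if (length(unknown))
      stop("no descriptors for chemical(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    df <- merge(df[, setdiff(names(df), c("log_kow", "log_hlc"))],
                chems[, c("name", "log_kow", "log_hlc")],
                by = "name", sort = FALSE)
  }
  req <- setdiff(c("log_kow", "ratio"), names(df))
  if (length(req))
    stop("calibration data lack column(s): ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!"log_hlc" %in% names(df)) df$log_hlc <- NA_real_
  if (!"name" %in% names(df)) df$name <- sprintf("obs_%03d", seq_len(nrow(df)))
  if (average_replicates && anyDuplicated(df$name)) {
    df <- stats::aggregate(
      df[, c("log_kow", "log_hlc", "ratio")],
      by = list(name = df$name),
      FUN = function(v) mean(v, na.rm = FALSE))
  }
  df[, c("name", "log_kow", "log_hlc", "ratio")]
}

# Expected squared residual E[(clip(mu+e,0,1)-mu)^2] for e ~ N(0, s^2):
# censoring at the admissible [0,1] range shrinks residuals near the
# boundaries, so the plain SSE/dof underestimates the noise SD.
.censored_m2 <- function(mu, s) {
  a <- (0 - mu) / s
  b <- (1 - mu) / s
  s^2 * (stats::pnorm(b) - stats::pnorm(a) -
           b * stats::dnorm(b) + a * stats::dnorm(a)) +
    mu^2 * stats::pnorm(a) + (1 - mu)^2 * (1 - stats::pnorm(b))
}

# Method-of-moments noise variance under boundary censoring: the sigma
# whose expected squared residuals (given the fitted curve) total the
# observed SSE, with the usual n/(n - n_par) degrees-of-freedom inflation.
# Falls back to SSE/dof when the fit is exact or the moments cannot match.
.censored_sigma2 <- function(pred, res, n_par = 4L) {
  sse <- sum(res^2)
  n <- length(res)
  dof <- max(n - n_par, 1L)
  if (sse < 1e-16) return(sse / dof)
  f <- function(s) sum(.censored_m2(pred, s)) - sse
  if (f(1) < 0) return(sse / dof)
  s <- stats::uniroot(f, c(1e-8, 1))$root
  s^2 * n / (n - n_par)
}

.predict_vec <- function(p, log_kow, log_hlc) {
  vol <- ifelse(is.na(log_hlc), 0, pmax(log_hlc + p[3], 0))
  x <- log_kow + p[2] * vol
  1 / (1 + 10^((p[1] - x) * p[4]))
}

# Finite-difference Jacobian of the model prediction w.r.t. the four
# parameters (central differences); n x 4.
.model_jacobian <- function(p, log_kow, log_hlc, h_rel = 1e-6) {
  J <- matrix(NA_real_, length(log_kow), 4L)
  for (j in 1:4) {
    h <- h_rel * max(1, abs(p[j]))
    up <- dn <- p
    up[j] <- p[j] + h
    dn[j] <- p[j] - h
    J[, j] <- (.predict_vec(up, log_kow, log_hlc) -
               .predict_vec(dn, log_kow, log_hlc)) / (2 * h)
  }
  J
}

#' Solver settings for [fit_loss_model()]
#'
#' Objective and step tolerances of 1e-6, at most 400 iterations and 600
#' function evaluations, mirroring the options the model was originally
#' calibrated with (the Levenberg-Marquardt solver used here is equivalent
#' in intent, not bit-identical, to that trust-region implementation).
#'
#' @param ftol,ptol relative tolerances on the objective and the parameters.
#' @param maxiter maximum iterations.
#' @param maxfev maximum residual evaluations.
#' @return A list of control settings.
#' @export
loss_fit_control <- function(ftol = 1e-6, ptol = 1e-6,
                             maxiter = 400, maxfev = 600) {
  list(ftol = ftol, ptol = ptol, maxiter = maxiter, maxfev = maxfev)
}

#' Fit the sigmoid loss model to measured ratios
#'
#' Nonlinear least-squares calibration of the four parameters of
#' [predict_ratio()] against measured C(t)/C(0) ratios, by
#' Levenberg-Marquardt minimisation of the residual sum of squares
#' ([minpack.lm::nls.lm]). Replicate records of one chemical are averaged
#' before fitting; optional inverse-variance weighting by the reported
#' replicate standard deviations is available but off by default. The
#' parameters are unbounded; the kink of the volatility term at
#' logHLC = -p3 is handled by the derivative-free-compatible solver with
#' finite-difference Jacobians. A softplus-smoothed variant of the kink
#' (sharpness 50) can be enabled for gradient stability.
#'
#' @param data a [as_ratio_records] table (or any data.frame with `name`
#'   and `ratio`, plus `log_kow`/`log_hlc` when `chems` is `NULL`).
#' @param chems a [chemicals] table supplying descriptors, matched by name.
#' @param start starting parameters, a [cover_params]; default
#'   [starting_params()].
#' @param weights `"none"` (default) or `"inverse_variance"` (uses 1/sd^2
#'   where a finite positive `sd` column is present).
#' @param average_replicates average replicate rows per chemical first.
#' @param smooth_kink replace max(u, 0) by softplus log(1+exp(50 u))/50.
#' @param sigma_method residual-variance estimator behind the parameter
#'   covariance and prediction bounds: `"censored_mm"` (default) solves
#'   for the noise SD whose boundary-censored expected squared residuals
#'   match the observed SSE, since measured ratios live in \[0, 1\] and
#'   censoring shrinks residuals near the boundaries; `"sse_dof"` is the
#'   plain SSE/(n - 4).
#' @param control solver settings, see [loss_fit_control()].
#' @return An object of class `loss_fit`: fitted [cover_params], the 4x4
#'   parameter covariance, `sse`, `r2` (squared Pearson correlation between
#'   predicted and observed), `adj_r2`, `dof` (n - 4), `rmse` (computed
#'   with the n - 1 denominator), per-parameter 95% confidence intervals,
#'   and convergence information.
#' @examples
#' set.seed(1)
#' chems <- generate_chemicals(30, seed = 1)
#' obs <- simulate_ratios(chems, cover_params(4, 1.29, 6.18, -1),
#'                        noise_sd = 0, seed = 2)
#' fit <- fit_loss_model(obs, chems)
#' fit
#' @export
fit_loss_model <- function(data, chems = NULL, start = starting_params(),
                           weights = c("none", "inverse_variance"),
                           average_replicates = TRUE,
                           smooth_kink = FALSE,
                           sigma_method = c("censored_mm", "sse_dof"),
                           control = loss_fit_control()) {
  stopifnot(inherits(start, "cover_params"))
  weights <- match.arg(weights)
  sigma_method <- match.arg(sigma_method)
  df <- .calibration_frame(data, chems, average_replicates)
  w <- rep(1, nrow(df))
  if (weights == "inverse_variance" && "sd" %in% names(as.data.frame(data))) {
    sdv <- as.data.frame(data)$sd
    if (!average_replicates && length(sdv) == nrow(df) &&
        all(is.finite(sdv)) && all(sdv > 0)) w <- 1 / sdv^2
  }

  p0 <- c(start$p1, start$p2, start$p3, start$p4)
  x0 <- df$log_kow + p0[2] *
    ifelse(is.na(df$log_hlc), 0, pmax(df$log_hlc + p0[3], 0))
  if (length(unique(round(x0, 10))) < 5)
    stop("insufficient data: need >= 5 records with distinct effective x",
         call. = FALSE)

  pred_fun <- if (smooth_kink) {
    function(p, kow, hlc) {
      u <- ifelse(is.na(hlc), -Inf, hlc + p[3])
      vol <- ifelse(is.finite(u), log1p(exp(pmin(50 * u, 700))) / 50, 0)
      1 / (1 + 10^((p[1] - (kow + p[2] * vol)) * p[4]))
    }
  } else .predict_vec

  resid_fun <- function(p)
    sqrt(w) * (df$ratio - pred_fun(p, df$log_kow, df$log_hlc))
  lm_fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, ptol = control$ptol,
      maxiter = control$maxiter, maxfev = control$maxfev))

  p_hat <- unname(lm_fit$par)
  pred <- .predict_vec(p_hat, df$log_kow, df$log_hlc)
  res <- df$ratio - pred
  n <- nrow(df)
  sse <- sum(res^2)
  dof <- n - 4L
  sigma2 <- if (dof <= 0) NA_real_
  else if (sigma_method == "censored_mm") .censored_sigma2(pred, res)
  else sse / dof

  J <- .model_jacobian(p_hat, df$log_kow, df$log_hlc)
  jtj <- crossprod(J)
  covariance <- tryCatch(sigma2 * solve(jtj), error = function(e) {
    warning("singular Jacobian: parameter covariance unavailable",
            call. = FALSE)
    matrix(NA_real_, 4, 4)
  })
  dimnames(covariance) <- list(c("p1", "p2", "p3", "p4"),
                               c("p1", "p2", "p3", "p4"))
  se <- sqrt(diag(covariance))
  tq <- if (dof > 0) stats::qt(0.975, dof) else NA_real_
  ci95 <- cbind(lower = p_hat - tq * se, upper = p_hat + tq * se)
  rownames(ci95) <- c("p1", "p2", "p3", "p4")

  gof <- goodness_of_fit(pred, df$ratio, n_par = 4L)
  fitted_params <- cover_params(p_hat[1], p_hat[2], p_hat[3], p_hat[4],
                                cover = start$cover,
                                provenance = "fitted", n_calibration = n)
  structure(list(params = fitted_params,
                 estimate = stats::setNames(p_hat,
                                            c("p1", "p2", "p3", "p4")),
                 covariance = covariance, ci95 = ci95,
                 sse = sse, r2 = gof$r2, adj_r2 = gof$adj_r2,
                 rmse = gof$rmse, dof = dof, sigma2 = sigma2,
                 converged = lm_fit$info %in% 1:3,
                 n_iter = lm_fit$niter, n_obs = n,
                 data = df, start = p0),
            class = "loss_fit")
}

#' @export
print.loss_fit <- function(x, ...) {
  cat("Sigmoid loss-model fit (", x$n_obs, " chemicals)\n", sep = "")
  est <- cbind(estimate = x$estimate, x$ci95)
  print(round(est, 4))
  cat(sprintf("R2 = %.4f  adj. R2 = %.4f  SSE = %.4g  RMSE = %.4g  dof = %d\n",
              x$r2, x$adj_r2, x$sse, x$rmse, x$dof))
  cat("converged:", x$converged, " iterations:", x$n_iter, "\n")
  invisible(x)
}

#' Goodness-of-fit statistics for predicted vs observed ratios
#'
#' `r2` is the squared Pearson correlation between predicted and observed
#' values (so it is invariant under affine rescaling of either vector);
#' `rmse` uses the n - 1 denominator, `rmse = sqrt(sse / (n - 1))`;
#' `adj_r2` adjusts for the number of fitted parameters.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @param n_par number of fitted parameters charged against the degrees of
#'   freedom (4 for the loss model).
#' @return A list with `r2`, `sse`, `rmse`, `adj_r2` and `dof`.
#' @examples
#' goodness_of_fit(c(0.2, 0.5, 0.8), c(0.1, 0.5, 0.9))
#' @export
goodness_of_fit <- function(predicted, observed, n_par = 4L) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  rmse <- sqrt(sse / (n - 1))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance: r2 undefined", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- stats::cor(predicted, observed)^2
  }
  dof <- n - n_par
  adj_r2 <- if (dof > 0) 1 - (1 - r2) * (n - 1) / dof else NA_real_
  list(r2 = r2, sse = sse, rmse = rmse, adj_r2 = adj_r2, dof = dof)
}

#' Observation-level prediction bounds
#'
#' First-order (delta-method) prediction intervals for a new measured ratio
#' at each chemical: the predictive variance is the residual variance plus
#' the parameter-uncertainty term J V J', with a Student-t quantile on the
#' fit's residual degrees of freedom. Intervals are pointwise (not
#' simultaneous) and are clipped to the physically admissible \[0, 1\].
#'
#' @param fit a converged [fit_loss_model()] result.
#' @param chems a [chemicals] table of prediction points.
#' @param level interval coverage, default 0.95.
#' @return data.frame with `name`, `fit`, `lwr`, `upr`.
#' @export
prediction_bounds <- function(fit, chems, level = 0.95) {
  stopifnot(inherits(fit, "loss_fit"))
  if (!fit$converged)
    stop("prediction bounds require a converged fit", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (any(!is.finite(fit$covariance)))
    stop("singular parameter covariance: bounds unavailable", call. = FALSE)
  chems <- as_chemicals(as.data.frame(chems))
  p <- unname(fit$estimate)
  pred <- .predict_vec(p, chems$log_kow, chems$log_hlc)
  J <- .model_jacobian(p, chems$log_kow, chems$log_hlc)
  var_pred <- fit$sigma2 + rowSums((J %*% fit$covariance) * J)
  half <- stats::qt(1 - (1 - level) / 2, fit$dof) * sqrt(pmax(var_pred, 0))
  data.frame(name = chems$name, fit = pred,
             lwr = pmax(pred - half, 0), upr = pmin(pred + half, 1))
}

#' Repeated random-split cross-validation of the loss model
#'
#' In each repeat, a fraction `calib_frac` (default 80%) of the chemicals
#' is drawn at random without replacement as the calibration set, the model
#' is refitted on it, and the held-out chemicals are scored:
#' goodness-of-fit ([goodness_of_fit()]) and membership in the refitted
#' model's prediction bounds ([prediction_bounds()]). Aggregates are means
#' over repeats; the whole procedure is reproducible from the seed. A
#' repeat whose calibration draw is degenerate (too few distinct effective
#' x values, or a failed fit) is redrawn and logged, never silently
#' skipped. A strict k-fold partition mode is available for comparison
#' (`method = "kfold"`, k = round(1 / (1 - calib_frac))).
#'
#' @param data,chems as in [fit_loss_model()].
#' @param n_reps number of random splits (or k-fold cycles).
#' @param calib_frac fraction of chemicals used for calibration.
#' @param start starting parameters for each refit.
#' @param seed integer root seed for the split sequence.
#' @param level prediction-bound coverage used for the membership score.
#' @param method `"random_split"` (default) or `"kfold"`.
#' @return An object of class `loss_cv`: `mean_r2`, `mean_sse`,
#'   `mean_rmse`, `frac_in_bounds`, per-chemical out-of-bounds counts,
#'   number of evaluations, redraw count, `n_reps`, `seed`.
#' @seealso [outlier_attribution()]
#' @export
cross_validate <- function(data, chems = NULL, n_reps = 100,
                           calib_frac = 0.8, start = starting_params(),
                           seed = 1, level = 0.95,
                           method = c("random_split", "kfold")) {
  method <- match.arg(method)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (calib_frac <= 0 || calib_frac >= 1)
    stop("calib_frac must be in (0, 1)", call. = FALSE)
  df <- .calibration_frame(data, chems, average_replicates = TRUE)
  n <- nrow(df)
  n_calib <- max(5L, round(calib_frac * n))
  if (n_calib >= n)
    stop("not enough chemicals to hold any out", call. = FALSE)

  set.seed(as.integer(seed))
  r2s <- sses <- rmses <- numeric(0)
  out_events <- in_events <- stats::setNames(rep(0, n), df$name)
  n_eval <- 0L
  redraws <- 0L

  holdout_sets <- list()
  if (method == "kfold") {
    k <- max(2L, round(1 / (1 - calib_frac)))
  }

  score_split <- function(calib_idx) {
    fit <- tryCatch(
      suppressWarnings(fit_loss_model(df[calib_idx, , drop = FALSE],
                                      start = start)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        any(!is.finite(fit$covariance))) return(NULL)
    hold <- df[-calib_idx, , drop = FALSE]
    pred <- .predict_vec(unname(fit$estimate), hold$log_kow, hold$log_hlc)
    m <- nrow(hold)
    gof <- list(sse = sum((hold$ratio - pred)^2))
    gof$rmse <- sqrt(gof$sse / max(m - 1, 1))
    gof$r2 <- if (m >= 3 && stats::sd(pred) > 0 && stats::sd(hold$ratio) > 0)
      stats::cor(pred, hold$ratio)^2 else NA_real_
    pb <- prediction_bounds(fit, hold, level = level)
    inside <- hold$ratio >= pb$lwr & hold$ratio <= pb$upr
    list(gof = gof, inside = inside, names = hold$name)
  }

  record <- function(sc) {
    r2s <<- c(r2s, sc$gof$r2)
    sses <<- c(sses, sc$gof$sse)
    rmses <<- c(rmses, sc$gof$rmse)
    n_eval <<- n_eval + length(sc$inside)
    out <- sc$names[!sc$inside]
    if (length(out))
      out_events[out] <<- out_events[out] + 1
    inn <- sc$names[sc$inside]
    if (length(inn))
      in_events[inn] <<- in_events[inn] + 1
  }

  for (rep_i in seq_len(n_reps)) {
    if (method == "random_split") {
      sc <- NULL
      tries <- 0L
      while (is.null(sc)) {
        tries <- tries + 1L
        if (tries > 100L)
          stop("calibration split degenerate after 100 redraws",
               call. = FALSE)
        idx <- sample.int(n, n_calib)
        sc <- score_split(idx)
        if (is.null(sc)) {
          redraws <- redraws + 1L
          message("cross_validate: redrawing degenerate split (repeat ",
                  rep_i, ")")
        }
      }
      record(sc)
    } else {
      fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        sc <- score_split(which(fold != f))
        if (is.null(sc)) {
          redraws <- redraws + 1L
          message("cross_validate: skipping degenerate fold ", f,
                  " (cycle ", rep_i, ")")
          next
        }
        record(sc)
      }
    }
  }

  structure(list(mean_r2 = mean(r2s, na.rm = TRUE),
                 mean_sse = mean(sses),
                 mean_rmse = mean(rmses),
                 frac_in_bounds = sum(in_events) / n_eval,
                 out_events = out_events,
                 eval_events = in_events + out_events,
                 n_eval = n_eval, redraws = redraws,
                 n_reps = n_reps, calib_frac = calib_frac,
                 method = method, level = level, seed = seed),
            class = "loss_cv")
}

#' @export
print.loss_cv <- function(x, ...) {
  cat("Cross-validation (", x$method, ", ", x$n_reps, " repeats, ",
      round(100 * x$calib_frac), "% calibration, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  mean R2 = %.4f  mean SSE = %.4g  mean RMSE = %.4g\n",
              x$mean_r2, x$mean_sse, x$mean_rmse))
  cat(sprintf("  %.1f%% of held-out values within %g%% prediction bounds\n",
              100 * x$frac_in_bounds, 100 * x$level))
  if (x$redraws) cat("  degenerate splits redrawn:", x$redraws, "\n")
  invisible(x)
}

#' Attribute out-of-bounds events to chemicals
#'
#' Ranks chemicals by the share of all out-of-prediction-bounds events they
#' account for across the cross-validation repeats. Shares sum to 1
#' whenever at least one event occurred; with no events the attribution is
#' empty.
#'
#' @param cv a [cross_validate()] result.
#' @return data.frame with `name`, `events`, `share`, sorted by decreasing
#'   share.
#' @export
outlier_attribution <- function(cv) {
  stopifnot(inherits(cv, "loss_cv"))
  total <- sum(cv$out_events)
  if (total == 0)
    return(data.frame(name = character(0), events = numeric(0),
                      share = numeric(0)))
  keep <- cv$out_events > 0
  out <- data.frame(name = names(cv$out_events)[keep],
                    events = unname(cv$out_events[keep]),
                    share = unname(cv$out_events[keep]) / total)
  out[order(-out$share), , drop = FALSE]
}
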