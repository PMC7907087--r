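# The empirical sigmoid loss model: fraction of the dosed chemical still in
# the exposure medium at the end of the assay, as a function of logKow and
# logHLC under one cover type.

#' Parameter set of the sigmoid loss model for one cover type
#'
#' The loss model predicts the remaining medium-concentration fraction
#' C(t)/C(0) as
#' \deqn{1 / (1 + 10^{(p1 - x) p4}), \quad
#'       x = \log K_{OW} + p2 \max(\log HLC + p3, 0)}
#' with four fitted parameters: `p1` the midpoint on the combined
#' hydrophobicity/volatility axis at which half the chemical is lost
#' (dimensionless), `p2` the weight of volatility relative to
#' hydrophobicity (per log unit of atm m^3 mol^-1), `p3` the offset whose
#' negative, -p3, is the volatility threshold on logHLC, and `p4` the slope
#' (dimensionless, negative for a loss curve).
#'
#' @param p1,p2,p3,p4 numeric model parameters, all finite.
#' @param cover label of the cover type the set was calibrated for:
#'   `"adhesive_foil"`, `"plastic_lid"`, `"aluminium_foil"` or `"custom"`.
#' @param provenance free-text note on where the values come from.
#' @param n_calibration number of chemicals behind the calibration, if any.
#' @return An object of class `cover_params`.
#' @examples
#' starting_params()
#' @seealso [predict_ratio()], [fit_loss_model()]
#' @export
cover_params <- function(p1, p2, p3, p4, cover = "custom",
                         provenance = NULL, n_calibration = NULL) {
  p <- c(p1 = as.numeric(p1), p2 = as.numeric(p2),
         p3 = as.numeric(p3), p4 = as.numeric(p4))
  if (any(!is.finite(p)))
    stop("all four loss-model parameters must be finite", call. = FALSE)
  cover <- match.arg(cover, c("adhesive_foil", "plastic_lid",
                              "aluminium_foil", "custom"))
  if (p[["p2"]] >= 0 && p[["p4"]] >= 0)
    warning("p4 >= 0 with p2 >= 0: parameters do not describe a loss curve",
            call. = FALSE)
  structure(list(cover = cover, p1 = p[["p1"]], p2 = p[["p2"]],
                 p3 = p[["p3"]], p4 = p[["p4"]],
                 provenance = provenance, n_calibration = n_calibration),
            class = "cover_params")
}

#' @export
print.cover_params <- function(x, ...) {
  cat("Loss-model parameters (", x$cover, ")\n", sep = "")
  cat(sprintf("  p1 = %.4g  p2 = %.4g  p3 = %.4g  p4 = %.4g\n",
              x$p1, x$p2, x$p3, x$p4))
  if (!is.null(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (!is.null(x$n_calibration))
    cat("  n_calibration:", x$n_calibration, "\n")
  invisible(x)
}

#' Documented starting values for loss-model calibration
#'
#' p1 = 4 (most tested chemicals have logKow between 0 and 8), p2 = 1
#' (volatility above threshold initially weighted like hydrophobicity),
#' p3 = 6 (mean of the water-derived 6.38 and the legacy 5.61 volatility
#' thresholds, sign-flipped) and p4 = -1 (default logistic slope).
#'
#' @param cover cover label to stamp on the set.
#' @return A [cover_params] object.
#' @export
starting_params <- function(cover = "custom") {
  cover_params(4, 1, 6, -1, cover = cover, provenance = "starting values")
}

.descriptor_cols <- function(chems) {
  if (is.data.frame(chems)) {
    if (!all(c("log_kow") %in% names(chems)))
      stop("chemical table lacks a log_kow column", call. = FALSE)
    list(log_kow = as.numeric(chems$log_kow),
         log_hlc = if ("log_hlc" %in% names(chems))
           as.numeric(chems$log_hlc) else rep(NA_real_, nrow(chems)))
  } else stop("chems must be a chemicals data.frame", call. = FALSE)
}

#' Combined hydrophobicity/volatility coordinate
#'
#' The model's single x-axis: `log_kow + p2 * max(log_hlc + p3, 0)`.
#' Below the volatility threshold (logHLC <= -p3) the volatility term is
#' exactly zero, so only hydrophobicity matters. A missing `log_hlc`
#' contributes zero as well (the chemical is treated as fully non-volatile)
#' and triggers a warning unless `warn_missing = FALSE`.
#'
#' @param chems a [chemicals] data.frame (columns `log_kow`, `log_hlc`).
#' @param params a [cover_params] object.
#' @param warn_missing warn when `log_hlc` is missing.
#' @return Numeric vector of effective x coordinates.
#' @export
effective_x <- function(chems, params, warn_missing = TRUE) {
  stopifnot(inherits(params, "cover_params"))
  d <- .descriptor_cols(chems)
  miss <- is.na(d$log_hlc)
  if (any(miss) && warn_missing)
    warning("missing log_hlc: volatility term set to 0 for ",
            sum(miss), " chemical(s)", call. = FALSE)
  vol <- ifelse(miss, 0, pmax(d$log_hlc + params$p3, 0))
  d$log_kow + params$p2 * vol
}

#' Predicted end-of-exposure medium-concentration ratio
#'
#' Forward evaluation of the sigmoid loss model: the fraction C(t)/C(0) of
#' the nominal concentration still present in the exposure medium at the
#' end of the exposure (24 h for the systems the model was built on). The
#' output is strictly within (0, 1) for finite inputs; the model does not
#' resolve kinetics within the exposure window.
#'
#' @inheritParams effective_x
#' @return Numeric vector of predicted ratios in (0, 1).
#' @examples
#' naph <- chemicals("naphthalene", 3.3, -3.36)
#' predict_ratio(naph, starting_params())
#' @export
predict_ratio <- function(chems, params, warn_missing = TRUE) {
  stopifnot(inherits(params, "cover_params"))
  x <- effective_x(chems, params, warn_missing = warn_missing)
  1 / (1 + 10^((params$p1 - x) * params$p4))
}

#' Summary exposure concentration over the assay
#'
#' Collapses the initial (nominal) and final medium concentrations into a
#' single exposure estimate. The geometric basis, nominal * sqrt(ratio), is
#' the convention for deriving exposure-corrected effect concentrations;
#' the arithmetic basis, nominal * (1 + ratio) / 2, matches data sets whose
#' EC50s were computed from arithmetic mean concentrations.
#'
#' @param nominal nominal (time 0) concentration, > 0; any unit.
#' @param ratio end-of-exposure ratio C(t)/C(0) in \[0, 1\].
#' @param basis `"geometric"` (default) or `"arithmetic"`.
#' @return Exposure concentration in the unit of `nominal`.
#' @examples
#' exposure_concentration(100, 0.25)                  # 50
#' exposure_concentration(100, 0.25, "arithmetic")    # 62.5
#' @export
exposure_concentration <- function(nominal, ratio,
                                   basis = c("geometric", "arithmetic")) {
  basis <- match.arg(basis)
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stop("nominal concentration must be > 0", call. = FALSE)
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 1))
    stop("ratio must lie in [0, 1]", call. = FALSE)
  if (basis == "geometric") {
    if (any(ratio == 0))
      warning("ratio of 0 gives a degenerate geometric mean of 0",
              call. = FALSE)
    nominal * sqrt(ratio)
  } else {
    nominal * (1 + ratio) / 2
  }
}
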