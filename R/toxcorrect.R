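# Exposure correction of effect concentrations and the agreement
# statistics built on it.

#' Convert a nominal EC50 to an exposure-corrected EC50
#'
#' Rescales a nominal effect concentration by the predicted (or measured)
#' end-of-exposure ratio of its assay: geometric basis multiplies by
#' sqrt(ratio) (the geometric mean of start and end concentrations),
#' arithmetic basis by (1 + ratio) / 2. A ratio of exactly 0 leaves the
#' corrected concentration undefined and is an error.
#'
#' @param ec50_nominal nominal EC50 (> 0, any consistent unit); vectorised.
#' @param ratio end-of-exposure ratio C(t)/C(0), in (0, 1\].
#' @param basis `"geometric"` (default) or `"arithmetic"`.
#' @return Corrected EC50 in the unit of `ec50_nominal`.
#' @examples
#' correct_ec50(10, 0.25)                # 5
#' correct_ec50(10, 0.25, "arithmetic")  # 6.25
#' @export
correct_ec50 <- function(ec50_nominal, ratio,
                         basis = c("geometric", "arithmetic")) {
  basis <- match.arg(basis)
  if (any(!is.finite(ec50_nominal)) || any(ec50_nominal <= 0))
    stop("ec50_nominal must be > 0", call. = FALSE)
  if (any(!is.finite(ratio)) || any(ratio <= 0) || any(ratio > 1))
    stop("ratio must lie in (0, 1]", call. = FALSE)
  if (basis == "geometric") ec50_nominal * sqrt(ratio)
  else ec50_nominal * (1 + ratio) / 2
}

#' Fraction of chemical pairs within an x-fold difference
#'
#' For each fold level x, the fraction of (EC50, LC50) pairs whose
#' symmetric fold difference max(EC50/LC50, LC50/EC50) is at most x. The
#' metric is two-sided and invariant under swapping the members of a pair;
#' the fraction is non-decreasing in x.
#'
#' @param ec50,lc50 positive concentration vectors of equal length.
#' @param folds fold levels, each >= 1; default the conventional 3, 5, 10.
#' @return Named numeric vector of fractions (names `"3-fold"` etc.).
#' @examples
#' xfold_agreement(c(1.1, 2.9, 6, 20), c(1, 1, 1, 1))
#' @export
xfold_agreement <- function(ec50, lc50, folds = c(3, 5, 10)) {
  if (length(ec50) == 0) stop("no pairs supplied", call. = FALSE)
  if (length(ec50) != length(lc50))
    stop("ec50 and lc50 must be matched vectors", call. = FALSE)
  if (any(ec50 <= 0) || any(lc50 <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  if (any(folds < 1)) stop("fold levels must be >= 1", call. = FALSE)
  fold_diff <- pmax(ec50 / lc50, lc50 / ec50)
  stats::setNames(vapply(folds, function(x) mean(fold_diff <= x),
                         numeric(1)),
                  paste0(folds, "-fold"))
}

#' F-test for the slope of an ordinary least-squares regression
#'
#' Tests whether y depends linearly on x: the F statistic for the slope of
#' y ~ x, with p from the F distribution on (1, n - 2) degrees of freedom.
#' A constant y gives F = 0, p = 1; an exact linear relation drives p to
#' the floating-point floor.
#'
#' @param x,y numeric vectors of equal length >= 3; x must vary.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
slope_f_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::sd(y) == 0)
    return(list(F = 0, p = 1, df1 = 1L, df2 = n - 2L))
  fit <- stats::lm(y ~ x)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  if (sse == 0) return(list(F = Inf, p = 0, df1 = 1L, df2 = n - 2L))
  Fstat <- ssr / (sse / (n - 2))
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
       df1 = 1L, df2 = n - 2L)
}

#' Medium-volume EC50 ratio analysis
#'
#' Compares effect concentrations obtained with two medium volumes for the
#' same chemicals. If medium volume played no toxicological role, the
#' EC50(volume 1)/EC50(volume 2) ratio would be 1 for every chemical;
#' differential chemical loss makes the nominal ratio drift above 1 for
#' hydrophobic/volatile chemicals. Correcting each EC50 by the geometric
#' exposure mean under its own volume's loss-model parameters multiplies
#' the nominal ratio by sqrt(r1)/sqrt(r2) and should remove that drift.
#' Both ratio sets are scored for the fraction of chemicals within 20% of
#' unity and regressed on the combined hydrophobicity/volatility
#' coordinate ([effective_x()] under the reference parameters) with
#' [slope_f_test()].
#'
#' @param ec50_a,ec50_b matched EC50 vectors for set-up A (e.g. 1 mL) and
#'   set-up B (e.g. 2 mL).
#' @param chems matched [chemicals] table.
#' @param params_a,params_b [cover_params] describing loss in the two
#'   set-ups.
#' @param tolerance half-width of the agreement band around 1 (default
#'   0.2).
#' @param criterion `"ratio"` scores |ratio - 1| <= tolerance (default);
#'   `"fold"` scores max(ratio, 1/ratio) <= 1 + tolerance.
#' @return List with `nominal_ratios`, `corrected_ratios`,
#'   `frac_within_nominal`, `frac_within_corrected`, `f_test_nominal`,
#'   `f_test_corrected`, `effective_x`.
#' @export
volume_ratio_analysis <- function(ec50_a, ec50_b, chems, params_a,
                                  params_b, tolerance = 0.2,
                                  criterion = c("ratio", "fold")) {
  criterion <- match.arg(criterion)
  chems <- as_chemicals(as.data.frame(chems))
  if (length(ec50_a) != length(ec50_b) ||
      length(ec50_a) != nrow(chems))
    stop("ec50 vectors and chemical table must be matched", call. = FALSE)
  if (any(ec50_a <= 0) || any(ec50_b <= 0))
    stop("EC50 values must be > 0", call. = FALSE)
  r_a <- predict_ratio(chems, params_a, warn_missing = FALSE)
  r_b <- predict_ratio(chems, params_b, warn_missing = FALSE)
  nominal <- ec50_a / ec50_b
  corrected <- nominal * sqrt(r_a) / sqrt(r_b)
  within <- function(ratio) {
    if (criterion == "ratio") mean(abs(ratio - 1) <= tolerance)
    else mean(pmax(ratio, 1 / ratio) <= 1 + tolerance)
  }
  x <- effective_x(chems, params_b, warn_missing = FALSE)
  list(nominal_ratios = nominal, corrected_ratios = corrected,
       frac_within_nominal = within(nominal),
       frac_within_corrected = within(corrected),
       f_test_nominal = slope_f_test(x, nominal),
       f_test_corrected = slope_f_test(x, corrected),
       effective_x = x)
}
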