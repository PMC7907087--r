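# Seeded synthetic data: chemicals spanning the calibration descriptor
# ranges, noisy loss observations from the forward model, and the frozen
# in-text fixture chemicals.

#' Describe a simulation of loss observations
#'
#' The defaults reproduce the calibration study conditions: descriptor
#' ranges logKow in \[-4.15, 6.5\] and logHLC in \[-12.1, -1.3\] (atm m^3
#' mol^-1, log10), true parameters (p1 = 4, p2 = 1.29, p3 = 6.18,
#' p4 = -1) for an adhesive-foil cover, and additive measurement noise of
#' SD 0.05 on the ratio scale.
#'
#' @param n_chemicals number of chemicals to draw.
#' @param kow_range,hlc_range descriptor ranges (low, high).
#' @param true_params generating [cover_params].
#' @param noise_sd SD of the additive Gaussian ratio noise, >= 0.
#' @param covers,volumes,times design labels stamped onto the simulated
#'   records (cover names, medium volumes in mL, sampling times in h).
#' @param seed integer seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_chemicals = 40,
                              kow_range = c(-4.15, 6.5),
                              hlc_range = c(-12.1, -1.3),
                              true_params = cover_params(
                                4, 1.29, 6.18, -1,
                                cover = "adhesive_foil",
                                provenance = "synthetic truth"),
                              noise_sd = 0.05,
                              covers = "adhesive_foil", volumes = 2,
                              times = 24, seed = 1) {
  stopifnot(inherits(true_params, "cover_params"))
  if (n_chemicals < 0) stop("n_chemicals must be >= 0", call. = FALSE)
  if (diff(kow_range) < 0 || diff(hlc_range) < 0)
    stop("descriptor ranges must be ordered (low, high)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_chemicals = n_chemicals, kow_range = kow_range,
                 hlc_range = hlc_range, true_params = true_params,
                 noise_sd = noise_sd, covers = covers, volumes = volumes,
                 times = times, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Draw synthetic chemicals over the descriptor ranges
#'
#' Descriptors are sampled uniformly and independently over the ranges;
#' `correlated = TRUE` instead couples volatility to hydrophobicity
#' (logHLC rank-correlated with logKow) for realism studies. Reproducible
#' from the seed.
#'
#' @param n number of chemicals.
#' @param kow_range,hlc_range descriptor ranges.
#' @param seed integer seed.
#' @param correlated couple logHLC to logKow.
#' @return A [chemicals] table with names `chem_001`, ...
#' @examples
#' generate_chemicals(5, seed = 42)
#' @export
generate_chemicals <- function(n, kow_range = c(-4.15, 6.5),
                               hlc_range = c(-12.1, -1.3), seed = 1,
                               correlated = FALSE) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0)
    return(as_chemicals(data.frame(name = character(0),
                                   log_kow = numeric(0))))
  set.seed(as.integer(seed))
  kow <- stats::runif(n, kow_range[1], kow_range[2])
  if (correlated) {
    u <- (kow - kow_range[1]) / diff(kow_range)
    jitter <- stats::runif(n, -0.25, 0.25)
    hlc <- hlc_range[1] + pmin(pmax(u + jitter, 0), 1) * diff(hlc_range)
  } else {
    hlc <- stats::runif(n, hlc_range[1], hlc_range[2])
  }
  chemicals(sprintf("chem_%03d", seq_len(n)), log_kow = kow, log_hlc = hlc)
}

#' Simulate noisy loss observations from the forward model
#'
#' Each chemical's true ratio comes from [predict_ratio()]; additive
#' Gaussian noise of SD `noise_sd` is applied on the ratio scale and the
#' result clipped to \[0, 1\], because a measured medium concentration can
#' neither exceed its starting value nor go negative. A logit-normal
#' alternative (`noise = "logit_normal"`, noise applied on the logit scale
#' with the same nominal SD) avoids the boundary clipping.
#'
#' @param chems a [chemicals] table.
#' @param params generating [cover_params].
#' @param noise_sd noise SD on the ratio scale, >= 0.
#' @param seed integer seed.
#' @param noise `"gaussian"` (clipped, default) or `"logit_normal"`.
#' @param cover,medium_volume_ml,time_h design labels for the records.
#' @return A [as_ratio_records] table.
#' @examples
#' chems <- generate_chemicals(10, seed = 1)
#' simulate_ratios(chems, starting_params(), noise_sd = 0.05, seed = 2)
#' @export
simulate_ratios <- function(chems, params, noise_sd = 0.05, seed = 1,
                            noise = c("gaussian", "logit_normal"),
                            cover = NULL, medium_volume_ml = 2,
                            time_h = 24) {
  noise <- match.arg(noise)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  chems <- as_chemicals(as.data.frame(chems))
  truth <- predict_ratio(chems, params, warn_missing = FALSE)
  set.seed(as.integer(seed))
  obs <- if (noise_sd == 0) {
    truth
  } else if (noise == "gaussian") {
    pmin(pmax(truth + stats::rnorm(length(truth), 0, noise_sd), 0), 1)
  } else {
    stats::plogis(stats::qlogis(pmin(pmax(truth, 1e-12), 1 - 1e-12)) +
                  stats::rnorm(length(truth), 0, noise_sd))
  }
  as_ratio_records(data.frame(name = chems$name,
                              cover = cover %||% params$cover,
                              medium_volume_ml = medium_volume_ml,
                              time_h = time_h, ratio = obs,
                              sd = noise_sd, n = 1L,
                              source = "simulated",
                              stringsAsFactors = FALSE))
}

#' Frozen in-text fixture chemicals
#'
#' The five chemicals whose descriptors are quoted in the main text of the
#' source experiments: difenoconazole (non-volatile, hydrophobic), DTBP
#' (2,4-di-tert-butylphenol; semi-volatile, hydrophobic), naphthalene
#' (volatile, less hydrophobic), propiconazole (non-volatile; HLC not
#' reported) and 3,4-dichloroaniline. The attached `design` attribute
#' records the cover-comparison experiment layout: sampling at 0, 4 and
#' 24 h, medium volumes 1 and 2 mL, covers plastic lid, adhesive foil and
#' aluminium foil.
#'
#' @return A [chemicals] table of 5 rows with a `design` attribute.
#' @export
intext_chemicals <- function() {
  out <- chemicals(
    name = c("difenoconazole", "2,4-di-tert-butylphenol", "naphthalene",
             "propiconazole", "3,4-dichloroaniline"),
    log_kow = c(4.3, 5.19, 3.3, 3.72, 2.69),
    log_hlc = c(-11.05, -5.43, -3.36, NA, -5.98))
  attr(out, "design") <- list(
    times_h = c(0, 4, 24), volumes_ml = c(1, 2),
    covers = c("plastic_lid", "adhesive_foil", "aluminium_foil"))
  out
}
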