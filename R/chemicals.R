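# Chemical descriptor handling: validation of logKow / logHLC records,
# Henry's Law Constant conversions and volatility classification.

#' Gas constant in atm m^3 mol^-1 K^-1
#'
#' Fixed to this unit system throughout the package so that Henry's Law
#' Constants expressed in atm m^3 mol^-1 convert to dimensionless air-water
#' partition coefficients without unit drift.
#'
#' @format A length-one numeric, 8.2057e-5 atm m^3 mol^-1 K^-1.
#' @export
R_ATM_M3 <- 8.2057e-5

#' Default assay temperature (K)
#'
#' The source experiments were run at 19-20 degrees C; 293.15 K (20 C) is
#' used wherever a temperature is needed and not supplied.
#'
#' @format A length-one numeric, 293.15 K.
#' @export
T_ASSAY_K <- 293.15

.chemical_columns <- c("name", "log_kow", "log_hlc", "mw",
                       "melting_point_c", "water_solubility")

#' Build a validated chemical descriptor table
#'
#' A chemical is described by its identity and two descriptors that drive
#' loss from the exposure medium: the log10 octanol-water partition
#' coefficient (`log_kow`, hydrophobicity) and the log10 Henry's Law
#' Constant in atm m^3 mol^-1 (`log_hlc`, volatility). Molar mass, melting
#' point and water solubility are carried along for mass-balance models that
#' need them.
#'
#' Validation enforces: `log_kow` finite and within \[-10, 12\] (a warning is
#' emitted outside the plausible range \[-5, 9\]); `log_hlc`, where present,
#' no greater than 2 (no super-gaseous chemicals). `log_hlc` may be `NA`,
#' meaning unknown/deeply non-volatile.
#'
#' @param name character vector of chemical names.
#' @param log_kow numeric, log10 octanol-water partition coefficient.
#' @param log_hlc numeric, log10 Henry's Law Constant (atm m^3 mol^-1);
#'   `NA` allowed.
#' @param mw optional molar mass (g mol^-1).
#' @param melting_point_c optional melting point (degrees C).
#' @param water_solubility optional water solubility (mol L^-1).
#' @return A `data.frame` of class `chemicals`.
#' @examples
#' chemicals("naphthalene", log_kow = 3.3, log_hlc = -3.36)
#' @seealso [as_chemicals()], [read_chemicals()], [intext_chemicals()]
#' @export
chemicals <- function(name, log_kow, log_hlc = NA_real_, mw = NA_real_,
                      melting_point_c = NA_real_,
                      water_solubility = NA_real_) {
  df <- data.frame(name = as.character(name),
                   log_kow = as.numeric(log_kow),
                   log_hlc = as.numeric(log_hlc),
                   mw = as.numeric(mw),
                   melting_point_c = as.numeric(melting_point_c),
                   water_solubility = as.numeric(water_solubility),
                   stringsAsFactors = FALSE)
  as_chemicals(df)
}

#' Coerce and validate a data frame of chemical descriptors
#'
#' @param x a data.frame with at least `name` and `log_kow` columns; the
#'   remaining descriptor columns are filled with `NA` when absent.
#' @return `x` with all descriptor columns, classed `chemicals`.
#' @export
as_chemicals <- function(x) {
  if (!is.data.frame(x))
    stop("chemicals must be given as a data.frame", call. = FALSE)
  missing_req <- setdiff(c("name", "log_kow"), names(x))
  if (length(missing_req))
    stop("chemical table lacks required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  for (col in setdiff(.chemical_columns, names(x)))
    x[[col]] <- rep(NA_real_, nrow(x))
  x <- x[, .chemical_columns, drop = FALSE]
  x$name <- as.character(x$name)
  for (col in .chemical_columns[-1]) x[[col]] <- as.numeric(x[[col]])

  bad <- !is.finite(x$log_kow)
  if (any(bad))
    stop("row ", which(bad)[1], ": log_kow required (finite value)",
         call. = FALSE)
  if (any(x$log_kow < -10 | x$log_kow > 12))
    stop("log_kow outside the supported range [-10, 12]", call. = FALSE)
  if (any(x$log_kow < -5 | x$log_kow > 9))
    warning("log_kow outside the plausible range [-5, 9]; check units",
            call. = FALSE)
  if (any(!is.na(x$log_hlc) & x$log_hlc > 2))
    stop("log_hlc > 2 is not physical for a dissolved chemical",
         call. = FALSE)
  class(x) <- c("chemicals", "data.frame")
  x
}

#' Dimensionless air-water partition coefficient
#'
#' Converts a Henry's Law Constant given as log10 atm m^3 mol^-1 into the
#' dimensionless air-water partition coefficient K_AW = HLC / (R T), the
#' form used by equilibrium mass-balance models.
#'
#' @param log_hlc log10 Henry's Law Constant (atm m^3 mol^-1); vectorised.
#' @param temperature absolute temperature in K (default [T_ASSAY_K]).
#' @return Numeric vector of dimensionless K_AW values.
#' @examples
#' dimensionless_kaw(-3.36)           # naphthalene, ~1.8e-2
#' dimensionless_kaw(-6.38)           # water, ~1.7e-5
#' @export
dimensionless_kaw <- function(log_hlc, temperature = T_ASSAY_K) {
  if (any(!is.finite(log_hlc)))
    stop("log_hlc must be finite", call. = FALSE)
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be a positive number of kelvin", call. = FALSE)
  10^log_hlc / (R_ATM_M3 * temperature)
}

#' Henry's Law Constant from vapour pressure and molar concentration
#'
#' For a pure liquid, HLC = vapour pressure / molar concentration of the
#' liquid phase. For water at 20 C (vapour pressure 0.023088 atm, density
#' 998.2 g L^-1, i.e. about 55409 mol m^-3) this gives log10 HLC of about
#' -6.38, the physical anchor for the volatility threshold of the loss
#' model.
#'
#' @param vapour_pressure vapour pressure in atm, > 0.
#' @param molar_concentration molar concentration of the condensed phase in
#'   mol m^-3, > 0.
#' @return log10 Henry's Law Constant (atm m^3 mol^-1).
#' @examples
#' log_hlc_from_vapour_pressure(0.023088, 998.2 / 18.015 * 1000)
#' @export
log_hlc_from_vapour_pressure <- function(vapour_pressure,
                                         molar_concentration) {
  if (any(!is.finite(vapour_pressure)) || any(vapour_pressure <= 0))
    stop("vapour_pressure must be > 0", call. = FALSE)
  if (any(!is.finite(molar_concentration)) || any(molar_concentration <= 0))
    stop("molar_concentration must be > 0", call. = FALSE)
  log10(vapour_pressure / molar_concentration)
}

#' Named volatility thresholds
#'
#' Two thresholds on log10 HLC are in circulation for splitting chemicals
#' into volatile and non-volatile: the literature value -5.61 (`"legacy"`)
#' and the threshold implied by the calibrated loss model for adhesive foil,
#' -6.18 (`"fitted"`, close to water's -6.38).
#'
#' @param preset `"legacy"` or `"fitted"`.
#' @return The threshold as log10 atm m^3 mol^-1.
#' @export
volatility_threshold <- function(preset = c("legacy", "fitted")) {
  preset <- match.arg(preset)
  c(legacy = -5.61, fitted = -6.18)[[preset]]
}

#' Classify chemicals as volatile or non-volatile
#'
#' A chemical is volatile iff its log10 HLC strictly exceeds the threshold.
#' Missing `log_hlc` is classified non-volatile with a warning: a chemical
#' whose HLC is unknown is treated as if the volatility term of the loss
#' model were inactive.
#'
#' @param log_hlc log10 Henry's Law Constant (atm m^3 mol^-1); vectorised,
#'   `NA` allowed.
#' @param threshold classification threshold; default the legacy -5.61,
#'   see [volatility_threshold()].
#' @return Character vector, `"volatile"` or `"non_volatile"`.
#' @examples
#' classify_volatility(c(-3.36, -11.05))
#' @export
classify_volatility <- function(log_hlc,
                                threshold = volatility_threshold("legacy")) {
  if (!is.finite(threshold))
    stop("threshold must be finite", call. = FALSE)
  if (any(is.na(log_hlc)))
    warning("missing log_hlc classified as non_volatile", call. = FALSE)
  ifelse(!is.na(log_hlc) & log_hlc > threshold, "volatile", "non_volatile")
}
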