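# Well-plate geometry bookkeeping and transfer of a calibrated loss model
# to a different plate set-up via compartment scale factors.

#' Derive a cylindrical well geometry
#'
#' Fills in the derived quantities of a cylindrical well: headspace volume
#' (total minus medium, exactly), bottom area pi (d/2)^2, wetted wall area
#' pi d h with fill height h = medium volume / bottom area, and foil area
#' equal to the well opening. The biological payload is carried as an
#' amount plus kind so that extrapolations can scale it.
#'
#' @param well_diameter_mm inner well diameter (mm), > 0.
#' @param total_well_volume_ml total well volume (mL), > 0.
#' @param medium_volume_ml medium volume (mL), 0 < medium < total.
#' @param plate_format `6`, `24`, `48` or `"custom"`.
#' @param biota `NULL`/`"none"`, or a list such as
#'   `list(kind = "cell_monolayer", count = 3e5, diameter_um = 15)` or
#'   `list(kind = "embryo", count = 1)`.
#' @return An object of class `well_geometry` with areas in cm^2 and
#'   volumes in mL.
#' @examples
#' well_geometry(15.6, 3.3, 2)   # a typical 24-well plate well
#' @export
well_geometry <- function(well_diameter_mm, total_well_volume_ml,
                          medium_volume_ml, plate_format = "custom",
                          biota = NULL) {
  if (!is.finite(well_diameter_mm) || well_diameter_mm <= 0)
    stop("well diameter must be > 0", call. = FALSE)
  if (!is.finite(total_well_volume_ml) || total_well_volume_ml <= 0)
    stop("total well volume must be > 0", call. = FALSE)
  if (!is.finite(medium_volume_ml) || medium_volume_ml <= 0)
    stop("medium volume must be > 0", call. = FALSE)
  if (medium_volume_ml >= total_well_volume_ml)
    stop("no headspace: medium volume must be below the total well volume",
         call. = FALSE)
  if (is.character(biota) && identical(biota, "none")) biota <- NULL
  d_cm <- well_diameter_mm / 10
  bottom_area_cm2 <- pi * (d_cm / 2)^2
  fill_height_cm <- medium_volume_ml / bottom_area_cm2   # 1 mL = 1 cm^3
  structure(list(plate_format = plate_format,
                 well_diameter_mm = well_diameter_mm,
                 total_well_volume_ml = total_well_volume_ml,
                 medium_volume_ml = medium_volume_ml,
                 headspace_volume_ml =
                   total_well_volume_ml - medium_volume_ml,
                 bottom_area_cm2 = bottom_area_cm2,
                 wetted_wall_area_cm2 = pi * d_cm * fill_height_cm,
                 foil_area_cm2 = bottom_area_cm2,
                 biota = biota),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat("Well geometry (", x$plate_format, "-well format)\n", sep = "")
  cat(sprintf("  diameter %.2f mm; total %.3g mL; medium %.3g mL; headspace %.3g mL\n",
              x$well_diameter_mm, x$total_well_volume_ml,
              x$medium_volume_ml, x$headspace_volume_ml))
  cat(sprintf("  bottom %.3f cm2; wetted wall %.3f cm2; foil %.3f cm2\n",
              x$bottom_area_cm2, x$wetted_wall_area_cm2, x$foil_area_cm2))
  if (!is.null(x$biota))
    cat("  biota:", x$biota$kind, "x", x$biota$count, "\n")
  invisible(x)
}

.biota_amount <- function(g) {
  if (is.null(g$biota)) return(0)
  as.numeric(g$biota$count %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compartment scale factors between two well set-ups
#'
#' Dimensionless factors describing how the per-volume capacity of each
#' loss pathway changes from a reference geometry to a new one:
#' `s_hydrophobic` scales the plastic-sorption pathway with
#' (A_plastic / V_W), `s_volatile` scales the headspace pathway with
#' (V_A / V_W), and `s_biota` scales the biological sink with
#' (biota amount / V_W). Identical geometries give all factors 1. The raw
#' plastic-area and headspace factors are also returned (e.g. halving the
#' medium of a 24-well plate from 2 mL to 1 mL halves the wetted plastic
#' and raises the headspace 1.76-fold).
#'
#' `plastic_convention` controls whether the wetted plastic is the wall
#' only (default; the well bottom is taken up by the cell monolayer and
#' foil scaling is separate) or wall plus bottom.
#'
#' @param ref,new [well_geometry()] objects.
#' @param plastic_convention `"wall_only"` or `"wall_plus_bottom"`.
#' @return List with `s_hydrophobic`, `s_volatile`, `s_biota`,
#'   `plastic_area_factor`, `headspace_factor`.
#' @examples
#' ref <- well_geometry(15.6, 3.3, 2)
#' new <- well_geometry(15.6, 3.3, 1)
#' geometry_scales(ref, new)
#' @export
geometry_scales <- function(ref, new,
                            plastic_convention = c("wall_only",
                                                   "wall_plus_bottom")) {
  stopifnot(inherits(ref, "well_geometry"), inherits(new, "well_geometry"))
  plastic_convention <- match.arg(plastic_convention)
  area <- function(g)
    g$wetted_wall_area_cm2 +
      if (plastic_convention == "wall_plus_bottom") g$bottom_area_cm2 else 0
  b_ref <- .biota_amount(ref)
  b_new <- .biota_amount(new)
  s_biota <- if (b_ref > 0)
    (b_new / new$medium_volume_ml) / (b_ref / ref$medium_volume_ml)
  else 1
  list(s_hydrophobic =
         (area(new) / new$medium_volume_ml) /
         (area(ref) / ref$medium_volume_ml),
       s_volatile =
         (new$headspace_volume_ml / new$medium_volume_ml) /
         (ref$headspace_volume_ml / ref$medium_volume_ml),
       s_biota = s_biota,
       plastic_area_factor = area(new) / area(ref),
       headspace_factor =
         new$headspace_volume_ml / ref$headspace_volume_ml)
}

#' Transfer a calibrated loss model to another well set-up
#'
#' Predicts the end-of-exposure ratio in a new geometry from parameters
#' calibrated in a reference geometry, without refitting. The loss odds
#' O = (1 - r) / r of each chemical are split into a hydrophobic part O_h
#' (the odds the chemical would have with its volatility term zeroed) and
#' a volatile part O_v = O - O_h >= 0; each part is scaled by the
#' corresponding compartment factor and the ratio is reassembled:
#' \deqn{r_{new} = 1 / (1 + O_h s_{hydrophobic} + O_v s_{volatile})}
#' This rule is the identity on the reference geometry and reduces to pure
#' hydrophobic scaling for non-volatile chemicals. It is a self-consistent
#' mass-balance-style transfer; when measured ratios exist for the new
#' set-up, refitting with [fit_loss_model()] is the preferred route.
#' Biota scaling is folded into the hydrophobic pathway by default (cell
#' sorption behaves as a hydrophobic sink); `biota_scaling = "separate"`
#' leaves the hydrophobic factor purely plastic-driven and multiplies O_h
#' by `s_biota` instead when the reference carries biota.
#'
#' @param chems a [chemicals] table.
#' @param params [cover_params] calibrated for `ref`.
#' @param ref,new [well_geometry()] objects.
#' @param plastic_convention passed to [geometry_scales()].
#' @param biota_scaling `"hydrophobic"` (default) or `"separate"`.
#' @return Numeric vector of predicted ratios in the new set-up.
#' @examples
#' p <- starting_params()
#' ref <- well_geometry(15.6, 3.3, 2)
#' new <- well_geometry(15.6, 3.3, 1)
#' naph <- chemicals("naphthalene", 3.3, -3.36)
#' extrapolate_ratio(naph, p, ref, new)
#' @export
extrapolate_ratio <- function(chems, params, ref, new,
                              plastic_convention = c("wall_only",
                                                     "wall_plus_bottom"),
                              biota_scaling = c("hydrophobic", "separate")) {
  stopifnot(inherits(params, "cover_params"))
  biota_scaling <- match.arg(biota_scaling)
  sc <- geometry_scales(ref, new, plastic_convention)
  r <- predict_ratio(chems, params, warn_missing = FALSE)
  odds <- (1 - r) / r
  # odds with the volatility term zeroed: only hydrophobicity drives loss
  d <- .descriptor_cols(chems)
  odds_h <- 10^((params$p1 - d$log_kow) * params$p4)
  odds_v <- odds - odds_h
  if (any(odds_v < -1e-9))
    stop("internal inconsistency: negative volatile odds component",
         call. = FALSE)
  odds_v <- pmax(odds_v, 0)
  mult_h <- if (biota_scaling == "separate" && .biota_amount(ref) > 0)
    sc$s_biota else sc$s_hydrophobic
  # identical geometries: exact identity, no odds round trip
  if (mult_h == 1 && sc$s_volatile == 1) return(r)
  1 / (1 + odds_h * mult_h + odds_v * sc$s_volatile)
}

#' Shipped default plate geometries
#'
#' Manufacturer-typical cylindrical dimensions for 6-, 24- and 48-well
#' polystyrene plates. These are assumed values for convenience, not
#' measured plate certificates; override them with [well_geometry()] or a
#' YAML file ([read_well_geometry()]) when exact dimensions are known.
#'
#' @param plate_format 6, 24 or 48.
#' @param medium_volume_ml medium volume (mL); defaults to the typical
#'   working volume of the format.
#' @param biota as in [well_geometry()].
#' @return A [well_geometry()] object.
#' @export
default_geometry <- function(plate_format, medium_volume_ml = NULL,
                             biota = NULL) {
  spec <- switch(as.character(plate_format),
    "6"  = list(d = 34.8, total = 16.8, medium = 3),
    "24" = list(d = 15.6, total = 3.3,  medium = 2),
    "48" = list(d = 11.6, total = 1.62, medium = 0.9),
    stop("no default geometry for a ", plate_format, "-well plate",
         call. = FALSE))
  well_geometry(spec$d, spec$total, medium_volume_ml %||% spec$medium,
                plate_format = as.character(plate_format), biota = biota)
}
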