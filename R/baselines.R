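# Mechanistic baseline models: equilibrium mass balance over the well
# compartments, and polystyrene-sorption depletion with an optional
# cell-lipid extension.

#' Specify an equilibrium mass-balance system for one well
#'
#' Describes the chemical-holding phases of a well at equilibrium: aqueous
#' medium, headspace air, serum albumin, serum lipid, dissolved organic
#' matter (DOM) and cells/tissue. Each non-aqueous phase is characterised
#' by its volume and its dimensionless partition coefficient against
#' water. Partition coefficients are user inputs; the model embeds no
#' property regressions.
#'
#' @param m_t total chemical amount in the well (mol), > 0.
#' @param v_w medium (water) volume (L), > 0.
#' @param v_a,v_sa,v_sl,v_d,v_c headspace, serum-albumin, serum-lipid, DOM
#'   and cell/tissue volumes (L), >= 0.
#' @param k_aw,k_saw,k_slw,k_dw,k_cw dimensionless partition coefficients
#'   of the corresponding phase against water, >= 0.
#' @return An object of class `armitage_system`.
#' @seealso [armitage_distribution()], [dimensionless_kaw()]
#' @export
armitage_system <- function(m_t, v_w, v_a = 0, v_sa = 0, v_sl = 0,
                            v_d = 0, v_c = 0, k_aw = 0, k_saw = 0,
                            k_slw = 0, k_dw = 0, k_cw = 0) {
  vols <- c(v_a = v_a, v_w = v_w, v_sa = v_sa, v_sl = v_sl,
            v_d = v_d, v_c = v_c)
  ks <- c(k_aw = k_aw, k_saw = k_saw, k_slw = k_slw,
          k_dw = k_dw, k_cw = k_cw)
  if (!is.finite(m_t) || m_t <= 0) stop("m_t must be > 0", call. = FALSE)
  if (any(!is.finite(vols)) || any(vols < 0))
    stop("volumes must be finite and >= 0", call. = FALSE)
  if (v_w <= 0) stop("medium volume v_w must be > 0", call. = FALSE)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("partition coefficients must be finite and >= 0", call. = FALSE)
  structure(list(m_t = m_t, v_a = v_a, v_w = v_w, v_sa = v_sa,
                 v_sl = v_sl, v_d = v_d, v_c = v_c, k_aw = k_aw,
                 k_saw = k_saw, k_slw = k_slw, k_dw = k_dw, k_cw = k_cw),
            class = "armitage_system")
}

#' Equilibrium chemical distribution across well compartments
#'
#' Solves the single-equation equilibrium mass balance: the freely
#' dissolved aqueous concentration is the total amount divided by the sum
#' of the volume-weighted capacities of all phases,
#' \deqn{C_W = M_T / (K_{AW} V_A + V_W + K_{SaW} V_{Sa} + K_{SlW} V_{Sl} +
#'       K_{DW} V_D + K_{CW} V_C)}
#' and each phase holds K_i V_i C_W mol (V_W C_W for the water phase).
#' Phase amounts sum to the dosed amount exactly (mass conservation).
#'
#' @param sys an [armitage_system()].
#' @return List with `c_w` (mol L^-1), `phase_amounts` (named mol vector
#'   over water, air, serum_albumin, serum_lipid, dom, cells) and
#'   `fraction_medium` (share of the dose residing in the aqueous phase).
#' @examples
#' sys <- armitage_system(m_t = 1e-6, v_w = 0.002, v_a = 0.0013, k_aw = 10)
#' armitage_distribution(sys)
#' @export
armitage_distribution <- function(sys) {
  stopifnot(inherits(sys, "armitage_system"))
  capacity <- c(water = sys$v_w,
                air = sys$k_aw * sys$v_a,
                serum_albumin = sys$k_saw * sys$v_sa,
                serum_lipid = sys$k_slw * sys$v_sl,
                dom = sys$k_dw * sys$v_d,
                cells = sys$k_cw * sys$v_c)
  denom <- sum(capacity)
  if (denom <= 0) stop("all capacity terms are zero", call. = FALSE)
  c_w <- sys$m_t / denom
  amounts <- capacity * c_w
  list(c_w = c_w, phase_amounts = amounts,
       fraction_medium = amounts[["water"]] / sys$m_t)
}

#' Polystyrene-water partition constant from hydrophobicity
#'
#' The regression log10 K_PS/W = 0.56 logKow - 0.05 linking sorption of an
#' organic chemical to polystyrene well-plate plastic with its
#' hydrophobicity.
#'
#' @param log_kow log10 octanol-water partition coefficient; vectorised.
#' @return log10 polystyrene-water partition constant.
#' @examples
#' fischer_log_kpsw(5.19)   # 2.8564
#' @export
fischer_log_kpsw <- function(log_kow) {
  if (any(!is.finite(log_kow))) stop("log_kow must be finite", call. = FALSE)
  0.56 * log_kow - 0.05
}

#' Equilibrium medium fraction under polystyrene sorption
#'
#' Fraction of the dosed chemical remaining in the medium once sorption to
#' the wetted plastic (and, optionally, partitioning into medium protein
#' and lipid and into cellular lipid) has equilibrated:
#' \deqn{f = V_W / (V_W + K_{PS/W} A + K_{lip} V_{lip} + K_{prot} V_{prot})}
#' K_PS/W comes from [fischer_log_kpsw()] and is applied here as a
#' medium-volume equivalent per wetted plastic area (L m^-2); that area
#' convention is explicit because the regression is published without
#' units (`kpsw_area_units`). The sorption endpoint is evaluated at
#' equilibrium; [approach_to_equilibrium()] provides the optional
#' first-order time course. Default surrogate partition coefficients for
#' lipid (10^logKow) and protein (0.05 x 10^logKow) are configurable and
#' are not literature-fitted values.
#'
#' @param log_kow chemical hydrophobicity; vectorised.
#' @param medium_volume_l medium volume (L), > 0.
#' @param wetted_area_m2 plastic area in contact with the medium (m^2).
#' @param protein_volume_l,lipid_volume_l medium protein and lipid volumes
#'   (L).
#' @param with_biota add `cell_lipid_volume_l` to the lipid phase.
#' @param cell_lipid_volume_l cellular lipid volume (L), see
#'   [cell_lipid_volume()].
#' @param k_lipid,k_protein lipid- and protein-water partition
#'   coefficients (dimensionless).
#' @param kpsw_area_units unit convention flag for K_PS/W (only
#'   `"L_per_m2"` is implemented).
#' @return Fraction of the dose remaining in the medium, in (0, 1\].
#' @examples
#' fischer_medium_fraction(1, medium_volume_l = 0.002,
#'                         wetted_area_m2 = 4e-4)
#' @export
fischer_medium_fraction <- function(log_kow, medium_volume_l,
                                    wetted_area_m2,
                                    protein_volume_l = 0,
                                    lipid_volume_l = 0,
                                    with_biota = FALSE,
                                    cell_lipid_volume_l = 0,
                                    k_lipid = 10^log_kow,
                                    k_protein = 0.05 * 10^log_kow,
                                    kpsw_area_units = "L_per_m2") {
  kpsw_area_units <- match.arg(kpsw_area_units, "L_per_m2")
  if (any(medium_volume_l <= 0))
    stop("medium volume must be > 0", call. = FALSE)
  if (any(c(wetted_area_m2, protein_volume_l, lipid_volume_l,
            cell_lipid_volume_l) < 0))
    stop("areas and volumes must be >= 0", call. = FALSE)
  kpsw <- 10^fischer_log_kpsw(log_kow)
  v_lip <- lipid_volume_l + if (with_biota) cell_lipid_volume_l else 0
  medium_volume_l / (medium_volume_l + kpsw * wetted_area_m2 +
                     k_lipid * v_lip + k_protein * protein_volume_l)
}

#' First-order approach to the sorption equilibrium
#'
#' Optional time course between the nominal start and the equilibrium
#' endpoint, C(t) = C_eq + (C_0 - C_eq) exp(-k t), with a user-supplied
#' rate constant.
#'
#' @param c0 starting concentration.
#' @param c_eq equilibrium concentration.
#' @param k first-order rate constant (per hour), >= 0.
#' @param time_h time points (h).
#' @return Concentrations at `time_h`.
#' @export
approach_to_equilibrium <- function(c0, c_eq, k, time_h) {
  if (any(k < 0)) stop("rate constant must be >= 0", call. = FALSE)
  c_eq + (c0 - c_eq) * exp(-k * time_h)
}

#' Total cellular lipid volume in a well
#'
#' Treats cells as spheres: `cell_count * (pi/6) diameter^3 *
#' lipid_fraction`, converted to litres. The defaults (300000 cells of
#' 15 um diameter, 5% lipid) describe a confluent RTgill-W1 monolayer in a
#' 24-well plate.
#'
#' @param cell_count number of cells, >= 0.
#' @param diameter_um cell diameter (um), >= 0.
#' @param lipid_fraction volumetric lipid fraction, in \[0, 1\].
#' @return Lipid volume in litres.
#' @examples
#' cell_lipid_volume()   # ~2.65e-8 L
#' @export
cell_lipid_volume <- function(cell_count = 3e5, diameter_um = 15,
                              lipid_fraction = 0.05) {
  if (any(cell_count < 0) || any(diameter_um < 0) ||
      any(lipid_fraction < 0) || any(lipid_fraction > 1))
    stop("inputs must be >= 0 (lipid_fraction in [0, 1])", call. = FALSE)
  # 1 um^3 = 1e-15 L
  cell_count * (pi / 6) * diameter_um^3 * lipid_fraction * 1e-15
}

#' Solubility sanity check for a dosing scheme
#'
#' Soft warning when the nominal dosed concentration exceeds the chemical's
#' water solubility, signalling that equilibrium-partitioning predictions
#' may not apply.
#'
#' @param nominal_mol_l nominal concentration (mol L^-1).
#' @param water_solubility_mol_l water solubility (mol L^-1); `NA` skips
#'   the check.
#' @return `TRUE` (invisibly) if within solubility or unknown.
#' @export
check_solubility <- function(nominal_mol_l, water_solubility_mol_l) {
  over <- !is.na(water_solubility_mol_l) &
    nominal_mol_l > water_solubility_mol_l
  if (any(over))
    warning("nominal concentration exceeds water solubility for ",
            sum(over), " chemical(s)", call. = FALSE)
  invisible(!any(over))
}
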