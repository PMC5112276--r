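## Open-system chamber gas exchange and isotope calculations.
##
## All operations are vectorized over cycles. Conventions:
##   * CO2 mole fractions (c_in, c_out) in umol mol^-1, used as measured (wet);
##     an optional dry-air correction is available in `compute_fluxes()`.
##   * water vapor mole fractions (w_in, w_out, w_leaf) in mol mol^-1.
##   * delta13C values in permil on the V-PDB scale at the user interface;
##     inside the discrimination equation they are converted to dimensionless
##     fractions (permil/1000), which is the only unit in which the
##     "1 + delta_out" term is consistent.

#' delta13C from isotopologue mole fractions
#'
#' delta13C = (x636/x626)/R_VPDB - 1, reported in permil. The 12C16O2 and
#' 13C16O2 mole fractions are the two isotopologues measured by the laser
#' spectrometer; rarer isotopologues are not part of the ratio.
#'
#' @param x626 12C16O2 mole fraction (umol mol^-1), must be > 0.
#' @param x636 13C16O2 mole fraction (umol mol^-1).
#' @param r_vpdb 13C/12C ratio of the V-PDB standard.
#' @return delta13C in permil.
#' @export
compute_delta <- function(x626, x636, r_vpdb = R_VPDB) {
  if (any(x626 <= 0, na.rm = TRUE))
    stop("compute_delta: x626 must be > 0")
  ((x636 / x626) / r_vpdb - 1) * 1000
}

#' Transpiration from the chamber water vapor balance
#'
#' E = flow * (w_out - w_in) / (leaf_area * (1 - w_out)), the steady-state
#' flow-through balance with the dilution term for water vapor added by the
#' shoot itself.
#'
#' @param flow_molar Molar air flow through the chamber (mol s^-1).
#' @param w_in,w_out Water vapor mole fraction at inlet/outlet (mol mol^-1).
#' @param leaf_area Projected leaf area (m^2), > 0.
#' @return Transpiration in mmol H2O m^-2 s^-1.
#' @export
transpiration <- function(flow_molar, w_in, w_out, leaf_area) {
  if (any(leaf_area <= 0)) stop("transpiration: leaf_area must be > 0")
  if (any(w_out >= 1, na.rm = TRUE)) stop("transpiration: w_out must be < 1")
  1000 * flow_molar * (w_out - w_in) / (leaf_area * (1 - w_out))
}

#' Stomatal conductance to water vapor
#'
#' Inverts the transpiration equation for a well-stirred (fan-mixed) chamber
#' where boundary-layer resistance is negligible:
#' g_s = E * (1 - (w_leaf + w_out)/2) / (w_leaf - w_out), with the leaf
#' internal vapor mole fraction w_leaf = e_sat(T_leaf)/P assumed saturated.
#'
#' @param E Transpiration in mmol m^-2 s^-1.
#' @param w_out Chamber (outlet) water vapor mole fraction (mol mol^-1).
#' @param T_leaf Leaf temperature (degrees C).
#' @param pressure Ambient pressure (hPa).
#' @return g_s in mol H2O m^-2 s^-1; NA with attribute-free silence where
#'   w_leaf <= w_out (condensation regime, flagged by `compute_fluxes()`).
#' @export
stomatal_conductance <- function(E, w_out, T_leaf, pressure = 1013.25) {
  w_leaf <- e_sat(T_leaf) / pressure
  gs <- (E / 1000) * (1 - (w_leaf + w_out) / 2) / (w_leaf - w_out)
  gs[w_leaf <= w_out] <- NA_real_
  gs
}

#' Net assimilation from the chamber CO2 balance
#'
#' A_N = flow * (c_in - c_out) / leaf_area - E * c_out, where the second term
#' corrects for dilution of CO2 by transpired water vapor. Negative values at
#' night are net respiration.
#'
#' @inheritParams transpiration
#' @param c_in,c_out CO2 mole fractions at inlet/outlet (umol mol^-1).
#' @param E Transpiration in mmol m^-2 s^-1.
#' @return A_N in umol CO2 m^-2 s^-1.
#' @export
net_assimilation <- function(flow_molar, c_in, c_out, E, leaf_area) {
  if (any(leaf_area <= 0)) stop("net_assimilation: leaf_area must be > 0")
  flow_molar * (c_in - c_out) / leaf_area - (E / 1000) * c_out
}

#' Intercellular CO2 mole fraction
#'
#' c_i = ((g_c - E/2) * c_out - A_N) / (g_c + E/2) with g_c = g_s/1.6 the
#' stomatal conductance to CO2; the E/2 terms account for the net outward
#' molar flow through the stomata. ci/ca is reported against the chamber air
#' concentration c_out and clipped to [0, 1.5].
#'
#' @param A_N Net assimilation (umol m^-2 s^-1).
#' @param g_s Stomatal conductance to H2O (mol m^-2 s^-1).
#' @param E Transpiration (mmol m^-2 s^-1).
#' @param c_out Chamber CO2 mole fraction (umol mol^-1).
#' @return list with `c_i` (umol mol^-1) and `ci_ca` (unitless).
#' @export
intercellular_co2 <- function(A_N, g_s, E, c_out) {
  g_c <- g_s / 1.6
  e_mol <- E / 1000
  c_i <- ((g_c - e_mol / 2) * c_out - A_N) / (g_c + e_mol / 2)
  c_i[!is.na(g_s) & g_s <= 0] <- NA_real_
  ci_ca <- .clamp(c_i / c_out, 0, 1.5)
  list(c_i = c_i, ci_ca = ci_ca)
}

#' Soil respiration from the soil chamber CO2 balance
#'
#' SR = flow * (c_out - c_in) / soil_area, the steady-state flow-through
#' balance for the soil compartment.
#'
#' @inheritParams net_assimilation
#' @param soil_area Enclosed soil surface area (m^2), > 0.
#' @return SR in umol CO2 m^-2 s^-1.
#' @export
soil_respiration <- function(flow_molar, c_in, c_out, soil_area) {
  if (any(soil_area <= 0)) stop("soil_respiration: soil_area must be > 0")
  flow_molar * (c_out - c_in) / soil_area
}

#' On-line photosynthetic 13C discrimination
#'
#' With xi = c_in / (c_in - c_out) and delta values as dimensionless
#' fractions d = delta/1000:
#' Delta = xi * (d_out - d_in) / (1 + d_out - xi * (d_out - d_in)),
#' returned in permil. Undefined (NA) when the CO2 draw-down is below the QC
#' threshold, where xi blows up.
#'
#' @param c_in,c_out CO2 mole fractions (umol mol^-1).
#' @param delta_in,delta_out delta13C of inlet/outlet CO2 (permil).
#' @param qc_threshold Minimum |c_in - c_out| (umol mol^-1).
#' @return list with `Delta` (permil) and `xi` (unitless), NA where undefined.
#' @export
discrimination_obs <- function(c_in, c_out, delta_in, delta_out,
                               qc_threshold = 5) {
  ok <- abs(c_in - c_out) > qc_threshold
  xi <- ifelse(ok, c_in / (c_in - c_out), NA_real_)
  d_in <- delta_in / 1000
  d_out <- delta_out / 1000
  num <- xi * (d_out - d_in)
  Delta <- 1000 * num / (1 + d_out - num)
  list(Delta = Delta, xi = xi)
}

#' delta13C of soil-respired CO2 by isotopic mass balance
#'
#' delta_SR = (delta_out * c_out - delta_in * c_in) / (c_out - c_in): the
#' two-end-member mixing inverse, so a source of known composition mixed into
#' any inlet stream is returned exactly. Linear in delta, so permil units pass
#' through unchanged.
#'
#' @inheritParams discrimination_obs
#' @param qc_threshold Minimum c_out - c_in (umol mol^-1).
#' @return delta13C of the respired CO2 in permil, NA where the soil CO2
#'   addition is below the QC threshold.
#' @export
delta_soil_respired <- function(c_in, c_out, delta_in, delta_out,
                                qc_threshold = 5) {
  ok <- (c_out - c_in) > qc_threshold
  ifelse(ok, (delta_out * c_out - delta_in * c_in) / (c_out - c_in), NA_real_)
}

#' Vapor pressure deficit
#'
#' VPD = e_sat(T_air) * (1 - RH/100) in hPa, using the Magnus saturation
#' formula (see [e_sat()]).
#'
#' @param T_air Air temperature (degrees C).
#' @param RH Relative humidity in percent, within [0, 100].
#' @param pressure Unused placeholder for interface symmetry.
#' @return VPD in hPa.
#' @export
vpd <- function(T_air, RH, pressure = 1013.25) {
  if (any(RH < 0 | RH > 100, na.rm = TRUE))
    stop("vpd: RH must be within [0, 100]")
  e_sat(T_air) * (1 - RH / 100)
}

#' Compute per-cycle fluxes and isotope signals from chamber cycles
#'
#' Applies the full set of open-system calculations to a calibrated cycles
#' table (see [parse_cycles()]): transpiration, stomatal conductance, net
#' assimilation and ci/ca for shoot chambers; soil respiration and the
#' delta13C of soil-respired CO2 for soil chambers; on-line discrimination for
#' shoot chambers inside the daytime PAR mask. QC flags are accumulated as
#' semicolon-joined tokens.
#'
#' @param cycles A cycles `data.table` from [parse_cycles()] (optionally
#'   through [apply_calibration()]).
#' @param leaf_area,soil_area Chamber areas (m^2).
#' @param pressure Ambient pressure (hPa).
#' @param qc_delta_c QC threshold on |c_in - c_out| for xi and the soil mass
#'   balance (umol mol^-1).
#' @param day_par PAR threshold (umol m^-2 s^-1) above which discrimination is
#'   reported.
#' @param dry_correction If TRUE, CO2 mole fractions are converted to a
#'   dry-air basis, c_dry = c / (1 - w), before the CO2 balances. Off by
#'   default: mole fractions are used as measured.
#' @return A `data.table` with one FluxRecord row per cycle.
#' @export
compute_fluxes <- function(cycles, leaf_area, soil_area, pressure = 1013.25,
                           qc_delta_c = 5, day_par = 500,
                           dry_correction = FALSE) {
  cy <- data.table::as.data.table(cycles)
  need <- c("plant_id", "compartment", "time_s", "c_in", "c_out",
            "delta_in", "delta_out", "w_in", "w_out", "flow_molar", "PAR",
            "T_air", "T_leaf", "RH")
  miss <- setdiff(need, names(cy))
  if (length(miss))
    stop("compute_fluxes: cycles table is missing column(s): ",
         paste(miss, collapse = ", "))

  c_in <- cy$c_in
  c_out <- cy$c_out
  if (dry_correction) {
    c_in <- c_in / (1 - cy$w_in)
    c_out <- c_out / (1 - cy$w_out)
  }
  flags <- if ("qc_flags" %in% names(cy)) cy$qc_flags else rep("", nrow(cy))
  shoot <- cy$compartment == "shoot"
  soil <- cy$compartment == "soil"

  out <- data.table::data.table(
    plant_id = cy$plant_id, compartment = cy$compartment,
    time_s = cy$time_s, PAR = cy$PAR,
    A_N = NA_real_, E = NA_real_, g_s = NA_real_,
    c_i = NA_real_, ci_ca = NA_real_, SR = NA_real_,
    Delta13C_obs = NA_real_, delta13C_SR = NA_real_, xi = NA_real_,
    VPD = vpd(cy$T_air, cy$RH, pressure)
  )

  if (any(shoot)) {
    e_tr <- transpiration(cy$flow_molar[shoot], cy$w_in[shoot],
                          cy$w_out[shoot], leaf_area)
    gs <- stomatal_conductance(e_tr, cy$w_out[shoot], cy$T_leaf[shoot],
                               pressure)
    an <- net_assimilation(cy$flow_molar[shoot], c_in[shoot], c_out[shoot],
                           e_tr, leaf_area)
    ci <- intercellular_co2(an, gs, e_tr, c_out[shoot])
    disc <- discrimination_obs(c_in[shoot], c_out[shoot], cy$delta_in[shoot],
                               cy$delta_out[shoot], qc_delta_c)
    night <- cy$PAR[shoot] <= day_par
    disc$Delta[night] <- NA_real_
    out[shoot, `:=`(E = e_tr, g_s = gs, A_N = an, c_i = ci$c_i,
                    ci_ca = ci$ci_ca, Delta13C_obs = disc$Delta,
                    xi = disc$xi)]
    fl <- flags[shoot]
    fl <- .add_flag(fl, is.na(gs) & !is.na(e_tr), "condensation")
    fl <- .add_flag(fl, is.na(disc$xi), "low_drawdown")
    fl <- .add_flag(fl, night, "night_mask")
    flags[shoot] <- fl
  }
  if (any(soil)) {
    sr <- soil_respiration(cy$flow_molar[soil], c_in[soil], c_out[soil],
                           soil_area)
    dsr <- delta_soil_respired(c_in[soil], c_out[soil], cy$delta_in[soil],
                               cy$delta_out[soil], qc_delta_c)
    out[soil, `:=`(SR = sr, delta13C_SR = dsr)]
    fl <- flags[soil]
    fl <- .add_flag(fl, sr < 0, "negative_SR")
    fl <- .add_flag(fl, is.na(dsr), "low_drawdown")
    flags[soil] <- fl
  }
  out[, qc_flags := flags]
  out[]
}
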