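## Shared physical constants and small conversion helpers.

#' Default 13C/12C isotope ratio of the V-PDB standard
#'
#' The Vienna-Pee Dee Belemnite ratio used to convert isotopologue mole
#' fractions to delta13C. A fixed published value; every function that uses it
#' accepts an `r_vpdb` argument so an alternative convention can be supplied.
#' @export
R_VPDB <- 0.0111802

# reference state for volumetric -> molar flow conversion (hPa, K)
.FLOW_REF_PRESSURE_PA <- 101325
.FLOW_REF_TEMP_K <- 298.15
.R_GAS <- 8.31446

#' Saturation vapor pressure (Magnus form)
#'
#' `e_sat(T) = 6.112 * exp(17.62 * T / (243.12 + T))` in hPa, valid for the
#' chamber temperature range (roughly -40 to 50 degrees C).
#'
#' @param temp_c Air or leaf temperature in degrees C.
#' @return Saturation vapor pressure in hPa.
#' @export
e_sat <- function(temp_c) {
  6.112 * exp(17.62 * temp_c / (243.12 + temp_c))
}

#' Convert a volumetric flow in l/min to a molar flow in mol/s
#'
#' Ideal-gas conversion at a fixed reference state (298.15 K, 1013.25 hPa)
#' because chamber flows are metered volumetrically. 10 l/min corresponds to
#' about 0.0068 mol/s.
#'
#' @param lpm Flow in liters per minute.
#' @param temp_k,pressure_pa Reference temperature (K) and pressure (Pa).
#' @return Molar flow in mol/s.
#' @export
flow_lpm_to_mol <- function(lpm, temp_k = .FLOW_REF_TEMP_K,
                            pressure_pa = .FLOW_REF_PRESSURE_PA) {
  stopifnot(all(lpm >= 0, na.rm = TRUE))
  lpm / 1000 / 60 * pressure_pa / (.R_GAS * temp_k)
}

# clamp a vector into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# semicolon-joined QC flag tokens; append `flag` where `where` is TRUE
.add_flag <- function(flags, where, flag) {
  where <- which(where)
  flags[where] <- ifelse(flags[where] == "", flag,
                         paste(flags[where], flag, sep = ";"))
  flags
}
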