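## Simulator configuration: a validated list of everything the synthetic
## chamber experiment needs, with defaults emulating a six-sapling
## control/drought beech experiment (3 control + 3 drought-treated plants,
## 16/8 h photoperiod with 3 h / 5 h light ramps to 600 umol m-2 s-1 PAR,
## soil moisture draw-down ~31 -> 24 %, daytime VPD rising from ~8.7 to
## ~17.1 hPa under drought, re-watering at 02:30 of the re-watering day,
## alternating 134 s inlet / 136 s outlet valve cycles, and delta13C noise
## consistent with an Allan deviation of 0.25 permil at 1 s).

#' Build a validated simulator configuration
#'
#' All arguments have defaults describing the emulated experiment; override
#' only what a scenario needs. `seed` is mandatory and drives every random
#' element (plant-to-plant trait scatter and measurement noise), so a given
#' config is fully reproducible.
#'
#' @param n_control,n_drought Number of plants per treatment arm.
#' @param days Length of the run in days.
#' @param drought_start_day Day index (0-based, may be negative to start the
#'   run mid-drought) at which irrigation of the drought arm is reduced.
#' @param rewater_day Day index of re-watering; day `rewater_day` begins with
#'   saturated soil (step at `rewater_hour`). Must be <= `days`; equal to
#'   `days` means the run ends before re-watering.
#' @param rewater_hour Hour of day of the re-watering step (2.5 = 02:30).
#' @param day_start_h Hour the light period begins.
#' @param photoperiod_h,ramp_up_h,ramp_down_h Light period length and linear
#'   ramp durations (h); `ramp_up_h + ramp_down_h < photoperiod_h`.
#' @param light_max Plateau PAR (umol m-2 s-1).
#' @param t_air_day,t_air_night Control air temperatures (deg C).
#' @param t_air_drought_offset_day,t_air_drought_offset_night Additional air
#'   warming of the drought arm at full drought intensity (deg C).
#' @param t_leaf_offset Daytime leaf-minus-air temperature offset (deg C).
#' @param t_soil,t_soil_amp,t_soil_drought_offset Soil temperature mean,
#'   diurnal amplitude and drought offset (deg C).
#' @param smc_control Control volumetric soil moisture (%).
#' @param smc_start,smc_drought_min Drought-arm soil moisture at onset and at
#'   its minimum (%).
#' @param smc_drawdown_days Days over which the drought-arm soil moisture
#'   declines linearly from `smc_start` to `smc_drought_min`; it then stays
#'   at the minimum until re-watering.
#' @param smc_rewet Soil moisture right after the re-watering step (%).
#' @param vpd_control_day,vpd_drought_day Daytime VPD of control plants and of
#'   drought plants at full drought intensity (hPa).
#' @param vpd_night Nighttime VPD (hPa).
#' @param vpd_recovery_tau_d e-folding time (days) with which the drought-arm
#'   VPD excess decays after re-watering.
#' @param gs_max Maximal stomatal conductance (mol m-2 s-1).
#' @param gs_g0_frac Residual (dark) conductance as a fraction of `gs_max`.
#' @param gs_par_half,gs_vpd_half PAR (umol m-2 s-1) and VPD (hPa)
#'   half-saturation constants of the conductance response.
#' @param gs_smc_min,gs_smc_ref Soil moisture (%) at stomatal closure and at
#'   no soil limitation.
#' @param an_a_max Maximal carboxylation-limited assimilation (umol m-2 s-1).
#' @param an_ci_half Half-saturation intercellular CO2 (umol mol-1).
#' @param an_par_half PAR half-saturation of the light response.
#' @param r_dark Dark respiration of the shoot (umol m-2 s-1, positive).
#' @param a_frac,b_frac Discrimination endpoints (permil): fractionation
#'   during diffusion (~4.4) and during carboxylation (~30);
#'   Delta_true = a + (b - a) * ci/ca.
#' @param sr_base Soil respiration at reference temperature and moist soil
#'   (umol m-2 s-1).
#' @param sr_t_ref,q10 Reference soil temperature (deg C) and Q10.
#' @param sr_smc_min,sr_smc_ref Soil moisture response bounds (%).
#' @param delta_sr_base Baseline delta13C of soil-respired CO2 (permil).
#' @param coupling_k Damping of the aboveground discrimination imprint on
#'   delta13C_SR, in [0, 1]; delta_SR(t) = delta_sr_base -
#'   k * (Delta_true(t - lag) - Delta_baseline).
#' @param coupling_lag_h Transport lag of that imprint (hours).
#' @param shoot_resp_delta delta13C of nighttime shoot-respired CO2 (permil).
#' @param c_in_ambient,delta_in_ambient CO2 mole fraction (umol mol-1) and
#'   delta13C (permil) of the inlet (climate chamber) air.
#' @param noise_delta13c Allan deviation of delta13C at 1 s averaging
#'   (permil); white noise is scaled by 1/sqrt(averaging time).
#' @param noise_co2 CO2 noise at 1 s (umol mol-1), same scaling.
#' @param noise_h2o Water vapor noise at 1 s (mol mol-1).
#' @param plant_cv Lognormal coefficient of variation of per-plant trait
#'   scatter (applied to `gs_max` and `sr_base`).
#' @param drift_gain_626,drift_gain_636 Total fractional multiplicative gain
#'   drift of each isotopologue channel over the whole run (0 = off).
#' @param cal_enabled Emit hourly calibration-gas blocks.
#' @param cal_co2,cal_delta Known calibration gas composition.
#' @param cal_every_h,cal_duration_s Calibration cadence and block length.
#' @param leaf_area,soil_area Chamber areas (m^2).
#' @param shoot_flow,soil_flow Chamber flows (l min-1).
#' @param inlet_s,outlet_s Valve cycle block lengths (s).
#' @param sample_period_s Spectrometer sample period (s); 2 s = 0.5 Hz.
#' @param multiplex If TRUE (default) a single analyzer visits all chambers
#'   round-robin, one chamber cycle per valve slot (as in the emulated
#'   experiment); if FALSE every chamber is recorded in every slot.
#' @param pressure Ambient pressure (hPa).
#' @param r_vpdb 13C/12C ratio of the reference standard.
#' @param seed Integer seed (mandatory).
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed,
                       n_control = 3, n_drought = 3,
                       days = 32, drought_start_day = 5, rewater_day = 22,
                       rewater_hour = 2.5,
                       day_start_h = 7, photoperiod_h = 16,
                       ramp_up_h = 3, ramp_down_h = 5, light_max = 600,
                       t_air_day = 25.4, t_air_night = 17.2,
                       t_air_drought_offset_day = 1.3,
                       t_air_drought_offset_night = 0.6,
                       t_leaf_offset = -0.8,
                       t_soil = 16.7, t_soil_amp = 0.3,
                       t_soil_drought_offset = 0.4,
                       smc_control = 30.9, smc_start = 31,
                       smc_drought_min = 24.1, smc_drawdown_days = 8,
                       smc_rewet = 33,
                       vpd_control_day = 8.7, vpd_drought_day = 17.1,
                       vpd_night = 4, vpd_recovery_tau_d = 1,
                       gs_max = 0.10, gs_g0_frac = 0.05,
                       gs_par_half = 100, gs_vpd_half = 15,
                       gs_smc_min = 20, gs_smc_ref = 30,
                       an_a_max = 35, an_ci_half = 1200, an_par_half = 250,
                       r_dark = 0.5,
                       a_frac = 4.4, b_frac = 30,
                       sr_base = 4.2, sr_t_ref = 16.7, q10 = 2,
                       sr_smc_min = 14, sr_smc_ref = 31,
                       delta_sr_base = -25.5, coupling_k = 0.15,
                       coupling_lag_h = 4, shoot_resp_delta = -26.5,
                       c_in_ambient = 420, delta_in_ambient = -9.3,
                       noise_delta13c = 0.25, noise_co2 = 0.1,
                       noise_h2o = 0, plant_cv = 0.03,
                       drift_gain_626 = 0, drift_gain_636 = 0,
                       cal_enabled = FALSE, cal_co2 = 400, cal_delta = -9.5,
                       cal_every_h = 1, cal_duration_s = 360,
                       leaf_area = 0.15, soil_area = 0.045,
                       shoot_flow = 14, soil_flow = 2.2,
                       inlet_s = 134, outlet_s = 136, sample_period_s = 2,
                       multiplex = TRUE, pressure = 1013.25,
                       r_vpdb = R_VPDB) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("sim_config: ", msg)
  chk(cfg$n_control >= 0 && cfg$n_drought >= 0 &&
        cfg$n_control + cfg$n_drought > 0, "need at least one plant")
  chk(cfg$days >= 0, "days must be >= 0")
  chk(cfg$rewater_day <= cfg$days,
      "rewater_day must be <= days (equal: run ends before re-watering)")
  chk(cfg$ramp_up_h + cfg$ramp_down_h < cfg$photoperiod_h ||
        (cfg$ramp_up_h == 0 && cfg$ramp_down_h == 0),
      "ramp_up_h + ramp_down_h must be < photoperiod_h")
  chk(cfg$day_start_h + cfg$photoperiod_h <= 24,
      "light period must end within the day")
  chk(all(c(cfg$leaf_area, cfg$soil_area, cfg$shoot_flow, cfg$soil_flow) > 0),
      "areas and flows must be > 0")
  chk(cfg$coupling_k >= 0 && cfg$coupling_k <= 1,
      "coupling_k must be in [0, 1]")
  chk(cfg$smc_drought_min < cfg$smc_start, "smc_drought_min < smc_start")
  chk(cfg$inlet_s > 0 && cfg$outlet_s > 0 && cfg$sample_period_s > 0,
      "valve timings must be > 0")
  chk(all(c(cfg$noise_delta13c, cfg$noise_co2, cfg$noise_h2o,
            cfg$plant_cv) >= 0), "noise terms must be >= 0")
  chk(cfg$gs_max > 0 && cfg$sr_base > 0, "gs_max and sr_base must be > 0")
  chk(cfg$b_frac > cfg$a_frac, "b_frac must exceed a_frac")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_control, "control +", x$n_drought,
      "drought plants,", x$days, "days, seed", x$seed, "\n")
  cat("  drought day", x$drought_start_day, "-> re-watering day",
      x$rewater_day, sprintf("(%02d:%02.0f)", floor(x$rewater_hour),
                             (x$rewater_hour %% 1) * 60), "\n")
  cat("  PAR", x$light_max, "umol m-2 s-1,", x$photoperiod_h, "h light;",
      "SMC", x$smc_start, "->", x$smc_drought_min, "%;",
      "VPD", x$vpd_control_day, "->", x$vpd_drought_day, "hPa\n")
  invisible(x)
}

# plant metadata table for a config
.sim_plants <- function(cfg) {
  data.table::data.table(
    plant_id = c(sprintf("C%d", seq_len(cfg$n_control)),
                 sprintf("D%d", seq_len(cfg$n_drought))),
    treatment = rep(c("control", "drought"),
                    c(cfg$n_control, cfg$n_drought))
  )
}
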