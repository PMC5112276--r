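## Synthetic chamber experiment: environmental drivers, ground-truth plant
## fluxes, and the raw valve-switched isotopologue stream that the ingest +
## flux pipeline consumes. The simulator works on the total-CO2 + delta scale
## and converts to isotopologue mole fractions last, so that the
## discrimination and mass-balance inversions are exact and a zero-noise run
## round-trips through the pipeline to machine precision.

# trapezoidal light schedule: fraction of light_max at hour-of-day h
.light_fraction <- function(h, cfg) {
  rel <- h - cfg$day_start_h
  up <- cfg$ramp_up_h
  down <- cfg$ramp_down_h
  plateau_end <- cfg$photoperiod_h - down
  f <- numeric(length(h))
  lit <- rel >= 0 & rel <= cfg$photoperiod_h
  if (up > 0) {
    i <- lit & rel < up
    f[i] <- rel[i] / up
  }
  i <- lit & rel >= up & rel <= plateau_end
  f[i] <- 1
  if (down > 0) {
    i <- lit & rel > plateau_end & rel <= cfg$photoperiod_h
    f[i] <- (cfg$photoperiod_h - rel[i]) / down
  }
  f
}

# drought intensity in [0,1] driven by the soil-moisture draw-down, and the
# post-re-watering decay used for the VPD / temperature excess
.drought_course <- function(t_s, cfg) {
  t_on <- cfg$drought_start_day * 86400
  t_rw <- cfg$rewater_day * 86400 + cfg$rewater_hour * 3600
  rate <- (cfg$smc_start - cfg$smc_drought_min) /
    (cfg$smc_drawdown_days * 86400)
  smc <- rep(cfg$smc_start, length(t_s))
  ramp <- t_s > t_on & t_s < t_rw
  smc[ramp] <- cfg$smc_start - rate * (t_s[ramp] - t_on)
  smc <- pmax(smc, cfg$smc_drought_min)
  after <- t_s >= t_rw
  smc[after] <- cfg$smc_rewet
  w <- (cfg$smc_start - smc) / (cfg$smc_start - cfg$smc_drought_min)
  w <- .clamp(w, 0, 1)
  # stress felt by the shoot (VPD, temperature) decays after re-watering
  w_shoot <- w
  if (any(after)) {
    w_rw <- (cfg$smc_start - cfg$smc_drought_min) /
      (cfg$smc_start - cfg$smc_drought_min)  # = 1 at re-watering
    w_shoot[after] <- w_rw *
      exp(-(t_s[after] - t_rw) / (cfg$vpd_recovery_tau_d * 86400))
  }
  list(smc = smc, w_shoot = w_shoot)
}

#' Generate environmental driver series for every plant
#'
#' Produces one row per plant and valve slot (one slot = one full
#' inlet + outlet cycle, 270 s by default) with drivers held constant within
#' a slot: PAR on a trapezoidal schedule, air/leaf/soil temperature, soil
#' moisture (linear draw-down from drought onset, step back at the
#' re-watering hour), VPD (prescribed, approaching `vpd_drought_day` for
#' drought plants and relaxing back after re-watering) and the consistent RH.
#'
#' @param cfg A [sim_config()].
#' @return A `data.table` with columns plant_id, treatment, slot, time_s,
#'   PAR, T_air, T_leaf, T_soil, SMC, VPD, RH.
#' @export
generate_environment <- function(cfg) {
  validate_sim_config(cfg)
  slot_len <- cfg$inlet_s + cfg$outlet_s
  n_slots <- floor(cfg$days * 86400 / slot_len)
  plants <- .sim_plants(cfg)
  grid <- data.table::CJ(plant_id = plants$plant_id, slot = seq_len(n_slots) - 1L,
                         sorted = FALSE)
  env <- plants[grid, on = "plant_id"]
  data.table::setorder(env, plant_id, slot)
  env[, time_s := slot * slot_len]
  mid <- env$time_s + slot_len / 2
  hod <- (mid / 3600) %% 24
  lf <- .light_fraction(hod, cfg)
  env[, PAR := cfg$light_max * lf]

  course <- .drought_course(mid, cfg)
  drt <- env$treatment == "drought"
  w <- ifelse(drt, course$w_shoot, 0)       # shoot-felt drought intensity
  env[, SMC := ifelse(drt, course$smc, cfg$smc_control)]

  t_day <- cfg$t_air_day + cfg$t_air_drought_offset_day * w
  t_night <- cfg$t_air_night + cfg$t_air_drought_offset_night * w
  env[, T_air := t_night + (t_day - t_night) * lf]
  env[, T_leaf := T_air + cfg$t_leaf_offset * lf]
  env[, T_soil := cfg$t_soil + cfg$t_soil_drought_offset * w +
        cfg$t_soil_amp * sin(2 * pi * (hod - 10) / 24)]

  vpd_day <- cfg$vpd_control_day +
    (cfg$vpd_drought_day - cfg$vpd_control_day) * w
  env[, VPD := cfg$vpd_night + (vpd_day - cfg$vpd_night) * lf]
  env[, RH := 100 * (1 - VPD / e_sat(T_air))]
  env[]
}

# supply/demand closure for one set of vectors; chamber CO2 balance included
# so that c_a equals the chamber (outlet) mole fraction. Returns A (umol
# m-2 s-1), c_i and c_out (umol mol-1). Rows with no positive root are dark.
.closure <- function(g_s, E_mol, Am, c_in, flow, leaf_area, K) {
  phi <- flow / leaf_area
  g_c <- g_s / 1.6
  alpha <- phi * c_in / (phi + E_mol)
  beta <- 1 / (phi + E_mol) + 1 / g_c
  B <- alpha + K + Am * beta
  disc <- B^2 - 4 * beta * Am * alpha
  A <- (B - sqrt(pmax(disc, 0))) / (2 * beta)
  ok <- disc >= 0 & Am > 0
  A[!ok] <- NA_real_
  c_out <- (phi * c_in - A) / (phi + E_mol)
  c_i <- alpha - beta * A
  list(A = A, c_i = c_i, c_out = c_out, ok = ok)
}

# closure evaluated at reference control daytime conditions; used as the
# baseline discrimination for the below-ground coupling
.baseline_Delta <- function(cfg) {
  f_par <- cfg$gs_g0_frac + (1 - cfg$gs_g0_frac) *
    cfg$light_max / (cfg$light_max + cfg$gs_par_half)
  f_vpd <- 1 / (1 + cfg$vpd_control_day / cfg$gs_vpd_half)
  f_smc <- .clamp((cfg$smc_control - cfg$gs_smc_min) /
                    (cfg$gs_smc_ref - cfg$gs_smc_min), 0.02, 1)
  g_s <- cfg$gs_max * f_smc * f_vpd * f_par
  T_air <- cfg$t_air_day
  T_leaf <- T_air + cfg$t_leaf_offset
  w_out <- (e_sat(T_air) - cfg$vpd_control_day) / cfg$pressure
  w_leaf <- e_sat(T_leaf) / cfg$pressure
  E_mol <- g_s * (w_leaf - w_out) / (1 - (w_leaf + w_out) / 2)
  Am <- cfg$an_a_max * cfg$light_max / (cfg$light_max + cfg$an_par_half)
  cl <- .closure(g_s, E_mol, Am, cfg$c_in_ambient,
                 flow_lpm_to_mol(cfg$shoot_flow), cfg$leaf_area,
                 cfg$an_ci_half)
  cfg$a_frac + (cfg$b_frac - cfg$a_frac) * cl$c_i / cl$c_out
}

#' Simulate ground-truth plant fluxes from environmental drivers
#'
#' Per plant and slot: stomatal conductance as
#' `gs_max * f_smc(SMC) * f_vpd(VPD) * f_par(PAR)` (all factors in (0, 1],
#' monotone); transpiration as the exact inverse of the pipeline's
#' conductance formula; net assimilation from the supply/demand closure
#' `A = (g_s/1.6) (c_a - c_i) = a_max L(PAR) c_i / (c_i + K)` solved jointly
#' with the chamber CO2 balance (so `c_a` is the chamber air concentration);
#' discrimination `Delta_true = a + (b - a) ci/ca`; soil respiration with a
#' Q10 temperature and linear soil moisture response; and delta13C of
#' soil-respired CO2 as a damped, lagged imprint of the aboveground
#' discrimination:
#' `delta_SR(t) = delta_sr_base - k (Delta_true(t - lag) - Delta_baseline)`.
#' Slots without a positive assimilation root (dark) get
#' `A_N = -r_dark` and undefined discrimination.
#'
#' Per-plant trait scatter (lognormal, `plant_cv`) on `gs_max` and `sr_base`
#' is drawn deterministically from the config seed.
#'
#' @param env Driver table from [generate_environment()].
#' @param cfg The same [sim_config()].
#' @return A `data.table` (the SimTruth): env columns plus g_s, E, A_N, c_i,
#'   ci_ca, c_a, Delta13C_true, SR_true, delta13C_SR_true, dark.
#' @export
simulate_plant_fluxes <- function(env, cfg) {
  validate_sim_config(cfg)
  tr <- data.table::copy(data.table::as.data.table(env))
  plants <- .sim_plants(cfg)
  set.seed(cfg$seed + 1L)
  traits <- plants[, .(plant_id,
                       gs_mult = exp(stats::rnorm(.N, 0, cfg$plant_cv)),
                       sr_mult = exp(stats::rnorm(.N, 0, cfg$plant_cv)))]
  tr <- traits[tr, on = "plant_id"]
  data.table::setorder(tr, plant_id, slot)

  f_par <- cfg$gs_g0_frac + (1 - cfg$gs_g0_frac) *
    tr$PAR / (tr$PAR + cfg$gs_par_half)
  f_vpd <- 1 / (1 + tr$VPD / cfg$gs_vpd_half)
  f_smc <- .clamp((tr$SMC - cfg$gs_smc_min) /
                    (cfg$gs_smc_ref - cfg$gs_smc_min), 0.02, 1)
  tr[, g_s := cfg$gs_max * gs_mult * f_smc * f_vpd * f_par]

  w_out <- (e_sat(tr$T_air) - tr$VPD) / cfg$pressure
  w_leaf <- e_sat(tr$T_leaf) / cfg$pressure
  E_mol <- tr$g_s * (w_leaf - w_out) / (1 - (w_leaf + w_out) / 2)
  tr[, E := 1000 * E_mol]

  Am <- cfg$an_a_max * tr$PAR / (tr$PAR + cfg$an_par_half)
  cl <- .closure(tr$g_s, E_mol, Am, cfg$c_in_ambient,
                 flow_lpm_to_mol(cfg$shoot_flow), cfg$leaf_area,
                 cfg$an_ci_half)
  dark <- tr$PAR < 5 | !cl$ok
  phi <- flow_lpm_to_mol(cfg$shoot_flow) / cfg$leaf_area
  A <- ifelse(dark, -cfg$r_dark, cl$A)
  tr[, A_N := A]
  tr[, c_a := (phi * cfg$c_in_ambient - A) / (phi + E_mol)]
  tr[, c_i := ifelse(dark, NA_real_, cl$c_i)]
  tr[, ci_ca := c_i / c_a]
  tr[, Delta13C_true := ifelse(dark, NA_real_,
                               cfg$a_frac + (cfg$b_frac - cfg$a_frac) * ci_ca)]
  tr[, dark := dark]

  h_smc <- .clamp((tr$SMC - cfg$sr_smc_min) /
                    (cfg$sr_smc_ref - cfg$sr_smc_min), 0.02, 1)
  tr[, SR_true := cfg$sr_base * sr_mult *
        cfg$q10^((T_soil - cfg$sr_t_ref) / 10) * h_smc]

  # lagged, damped above-ground imprint on the soil-respired delta13C;
  # nights carry the last lit value forward
  slot_len <- cfg$inlet_s + cfg$outlet_s
  lag_slots <- as.integer(round(cfg$coupling_lag_h * 3600 / slot_len))
  base_D <- .baseline_Delta(cfg)
  tr[, Delta_fill := data.table::nafill(Delta13C_true, type = "locf"),
     by = plant_id]
  tr[is.na(Delta_fill), Delta_fill := base_D]
  tr[, delta13C_SR_true := cfg$delta_sr_base - cfg$coupling_k *
        (data.table::shift(Delta_fill, lag_slots, fill = base_D) - base_D),
     by = plant_id]
  tr[, Delta_fill := NULL]
  tr[]
}

# convert total CO2 (umol mol-1) + delta13C (permil) to isotopologue pair
.to_isotopologues <- function(c_total, delta, r_vpdb) {
  r <- r_vpdb * (1 + delta / 1000)
  x636 <- c_total * r / (1 + r)
  list(x626 = c_total - x636, x636 = x636)
}

#' Synthesize the raw valve-switched isotopologue stream
#'
#' Inverts the pipeline's mass balances per chamber cycle to obtain the
#' outlet CO2, water vapor and delta13C consistent with the ground truth
#' (exact inversion of the discrimination equation for the shoot chamber and
#' of the two-member mixing equation for the soil chamber), splits total CO2
#' and delta into the 12C16O2 / 13C16O2 mole fractions, and emits samples at
#' `sample_period_s` in alternating inlet / outlet blocks. White Gaussian
#' noise scaled from the 1 s Allan deviation by 1/sqrt(sample period) is
#' added on the (CO2, delta) scale; an optional slow linear gain drift per
#' isotopologue channel and hourly calibration-gas blocks of known
#' composition can be injected.
#'
#' @param truth SimTruth table from [simulate_plant_fluxes()].
#' @param cfg The same [sim_config()].
#' @return A `data.table` raw stream, one row per sample: time_s, chamber_id,
#'   plant_id, compartment, line (inlet/outlet/cal), x626, x636, w_h2o, PAR,
#'   T_air, T_leaf, T_soil, SMC, RH, flow_lpm. Deterministic given the seed.
#' @export
synthesize_raw_stream <- function(truth, cfg) {
  validate_sim_config(cfg)
  tr <- data.table::as.data.table(truth)
  slot_len <- cfg$inlet_s + cfg$outlet_s
  flow_shoot <- flow_lpm_to_mol(cfg$shoot_flow)
  flow_soil <- flow_lpm_to_mol(cfg$soil_flow)

  # chamber-cycle boundary values (one row per plant, slot and compartment)
  sh <- tr[, .(plant_id, slot, time_s, PAR, T_air, T_leaf, T_soil, SMC, RH)]
  sh[, compartment := "shoot"]
  sh[, flow_lpm := cfg$shoot_flow]
  w_out <- (e_sat(tr$T_air) - tr$VPD) / cfg$pressure
  sh[, w_out := w_out]
  sh[, w_in := w_out - (tr$E / 1000) * cfg$leaf_area * (1 - w_out) / flow_shoot]
  sh[, c_in := cfg$c_in_ambient]
  sh[, c_out := tr$c_a]
  sh[, delta_in := cfg$delta_in_ambient]
  d_in <- cfg$delta_in_ambient / 1000
  xi <- sh$c_in / (sh$c_in - sh$c_out)
  Df <- tr$Delta13C_true / 1000
  u <- Df * (1 + d_in) / (xi - Df * (1 - xi))
  d_out_light <- d_in + u
  # dark: shoot respires CO2 of fixed composition into the chamber
  d_out_dark <- (d_in * sh$c_in +
                   (cfg$shoot_resp_delta / 1000) * (sh$c_out - sh$c_in)) /
    sh$c_out
  sh[, delta_out := 1000 * ifelse(tr$dark, d_out_dark, d_out_light)]

  so <- tr[, .(plant_id, slot, time_s, PAR, T_air, T_leaf, T_soil, SMC, RH)]
  so[, compartment := "soil"]
  so[, flow_lpm := cfg$soil_flow]
  so[, w_in := sh$w_in]
  so[, w_out := sh$w_in]
  so[, c_in := cfg$c_in_ambient]
  so[, c_out := c_in + tr$SR_true * cfg$soil_area / flow_soil]
  so[, delta_in := cfg$delta_in_ambient]
  so[, delta_out := (cfg$delta_in_ambient * c_in +
                       tr$delta13C_SR_true * (c_out - c_in)) / c_out]

  cycles <- rbind(sh, so)
  cycles[, chamber_id := paste(plant_id, compartment, sep = "_")]

  # analyzer schedule: round-robin over chambers (multiplex) or all chambers
  # every slot
  chambers <- cycles[, sort(unique(chamber_id))]
  n_ch <- length(chambers)
  if (isTRUE(cfg$multiplex) && n_ch > 1) {
    cycles[, ch_idx := match(chamber_id, chambers) - 1L]
    cycles <- cycles[slot %% n_ch == ch_idx]
    cycles[, ch_idx := NULL]
  }
  data.table::setorder(cycles, slot, chamber_id)

  n_in <- floor(cfg$inlet_s / cfg$sample_period_s)
  n_out <- floor(cfg$outlet_s / cfg$sample_period_s)
  n_per <- n_in + n_out
  idx <- rep(seq_len(nrow(cycles)), each = n_per)
  off <- rep(c(seq_len(n_in) - 1L, seq_len(n_out) - 1L), nrow(cycles))
  is_out <- rep(rep(c(FALSE, TRUE), c(n_in, n_out)), nrow(cycles))

  stream <- cycles[idx, .(chamber_id, plant_id, compartment,
                          PAR, T_air, T_leaf, T_soil, SMC, RH, flow_lpm)]
  stream[, time_s := cycles$time_s[idx] +
           ifelse(is_out, cfg$inlet_s, 0) + off * cfg$sample_period_s]
  stream[, line := ifelse(is_out, "outlet", "inlet")]
  c_tot <- ifelse(is_out, cycles$c_out[idx], cycles$c_in[idx])
  delta <- ifelse(is_out, cycles$delta_out[idx], cycles$delta_in[idx])
  stream[, w_h2o := ifelse(is_out, cycles$w_out[idx], cycles$w_in[idx])]

  # calibration blocks of known composition (their own line, no chamber)
  t_end <- max(cfg$days * 86400, slot_len)
  if (isTRUE(cfg$cal_enabled) && cfg$cal_every_h > 0) {
    cal_starts <- seq(0, t_end - cfg$cal_duration_s,
                      by = cfg$cal_every_h * 3600)
    n_cal <- floor(cfg$cal_duration_s / cfg$sample_period_s)
    cal <- data.table::data.table(
      time_s = rep(cal_starts, each = n_cal) +
        rep(seq_len(n_cal) - 1L, length(cal_starts)) * cfg$sample_period_s,
      chamber_id = "CAL", plant_id = NA_character_,
      compartment = NA_character_, line = "cal",
      PAR = NA_real_, T_air = NA_real_, T_leaf = NA_real_,
      T_soil = NA_real_, SMC = NA_real_, RH = NA_real_, flow_lpm = NA_real_,
      w_h2o = 0)
    c_tot <- c(c_tot, rep(cfg$cal_co2, nrow(cal)))
    delta <- c(delta, rep(cfg$cal_delta, nrow(cal)))
    stream <- rbind(stream, cal, fill = TRUE)
  }

  # white noise scaled from the 1 s Allan deviation
  set.seed(cfg$seed + 2L)
  n <- nrow(stream)
  sq <- sqrt(cfg$sample_period_s)
  if (cfg$noise_co2 > 0)
    c_tot <- c_tot + stats::rnorm(n, 0, cfg$noise_co2 / sq)
  if (cfg$noise_delta13c > 0)
    delta <- delta + stats::rnorm(n, 0, cfg$noise_delta13c / sq)
  if (cfg$noise_h2o > 0)
    stream[, w_h2o := w_h2o + stats::rnorm(n, 0, cfg$noise_h2o / sq)]

  iso <- .to_isotopologues(c_tot, delta, cfg$r_vpdb)
  stream[, x626 := iso$x626]
  stream[, x636 := iso$x636]
  if (cfg$drift_gain_626 != 0)
    stream[, x626 := x626 * (1 + cfg$drift_gain_626 * time_s / t_end)]
  if (cfg$drift_gain_636 != 0)
    stream[, x636 := x636 * (1 + cfg$drift_gain_636 * time_s / t_end)]

  data.table::setcolorder(stream, c("time_s", "chamber_id", "plant_id",
                                    "compartment", "line", "x626", "x636",
                                    "w_h2o", "PAR", "T_air", "T_leaf",
                                    "T_soil", "SMC", "RH", "flow_lpm"))
  data.table::setorder(stream, time_s, chamber_id)
  stream[]
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [generate_environment()],
#' [simulate_plant_fluxes()] and [synthesize_raw_stream()].
#'
#' @param cfg A [sim_config()].
#' @return list with elements `env`, `truth`, `stream` and `config`.
#' @export
simulate_experiment <- function(cfg) {
  env <- generate_environment(cfg)
  truth <- simulate_plant_fluxes(env, cfg)
  stream <- synthesize_raw_stream(truth, cfg)
  list(env = env, truth = truth, stream = stream, config = cfg)
}
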