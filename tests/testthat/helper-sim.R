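# Shared fixtures: small simulator configs and a hand-built raw stream.

# one fully droughted day (soil moisture already at its minimum), used for
# fast closed-loop and recovery-of-parameters tests
quick_drought_config <- function(seed, ...) {
  sim_config(seed = seed, days = 1, drought_start_day = -20, rewater_day = 1,
             ...)
}

noise_free_config <- function(seed, ...) {
  quick_drought_config(seed, noise_delta13c = 0, noise_co2 = 0,
                       plant_cv = 0, ...)
}

# join pipeline flux records back to simulator truth by plant and valve slot
join_truth <- function(flux, truth, slot_len = 270) {
  fx <- data.table::copy(flux)
  fx[, slot := floor(time_s / slot_len)]
  truth[fx, on = c("plant_id", "slot")]
}

max_rel_err <- function(est, ref) {
  ok <- !is.na(est) & !is.na(ref)
  max(abs(est[ok] - ref[ok]) / pmax(abs(ref[ok]), 1e-9))
}

# minimal hand-built stream: one chamber, given blocks of (line, duration,
# constant values); 0.5 Hz
build_stream <- function(blocks, chamber = "P1_shoot", plant = "P1",
                         compartment = "shoot", period = 2, t0 = 0) {
  rows <- list()
  t <- t0
  for (b in blocks) {
    n <- floor(b$dur / period)
    tt <- t + (seq_len(n) - 1) * period
    rows[[length(rows) + 1]] <- data.table::data.table(
      time_s = tt, chamber_id = chamber, plant_id = plant,
      compartment = compartment, line = b$line,
      x626 = if (length(b$x626) == 1) rep(b$x626, n) else b$x626,
      x636 = if (length(b$x636) == 1) rep(b$x636, n) else b$x636,
      w_h2o = b$w %||% 0.015,
      PAR = b$PAR %||% 600, T_air = 25, T_leaf = 24.2, T_soil = 16.7,
      SMC = 30, RH = 70, flow_lpm = 14)
    t <- t + b$dur
  }
  data.table::rbindlist(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# isotopologue pair for a given total CO2 and delta13C (independent of the
# package internals; used to build fixtures)
iso_pair <- function(c_total, delta, r = isochamber::R_VPDB) {
  rr <- r * (1 + delta / 1000)
  x636 <- c_total * rr / (1 + rr)
  list(x626 = c_total - x636, x636 = x636)
}
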