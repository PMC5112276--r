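## Raw-stream ingestion: turn the valve-switched 0.5 Hz isotopologue stream
## into averaged, calibrated, paired inlet/outlet chamber cycles.
##
## delta13C is computed from cycle-averaged isotopologue mole fractions
## (average first, then ratio): the ratio of means is less noise-biased than
## the mean of ratios at low signal-to-noise.

# recompute derived total CO2 and delta columns from (possibly calibrated)
# isotopologue means
.finalize_cycle_deltas <- function(cy, r_vpdb = R_VPDB, co2_scale = 1) {
  cy[, c_in := (x626_in + x636_in) * co2_scale]
  cy[, c_out := (x626_out + x636_out) * co2_scale]
  cy[, delta_in := compute_delta(x626_in, x636_in, r_vpdb)]
  cy[, delta_out := compute_delta(x626_out, x636_out, r_vpdb)]
  cy
}

# assign block ids within one chamber: a new block starts when the line label
# changes or the sampling is interrupted
.block_ids <- function(line, time_s, gap_tol) {
  new_block <- c(TRUE, line[-1] != line[-length(line)] |
                   diff(time_s) > gap_tol)
  cumsum(new_block)
}

#' Parse a raw stream into paired inlet/outlet chamber cycles
#'
#' Splits each chamber's sample series into contiguous inlet / outlet blocks,
#' discards the first `lag_s` seconds of every block (flushing lag after
#' valve switching), averages the isotopologue and environmental channels
#' over the remaining window, and pairs each inlet block with the immediately
#' following outlet block of the same chamber. Blocks whose total length is
#' below `lag_s + min_usable_s` are dropped, as are unpaired blocks; both are
#' counted in the `dropped` attribute of the result.
#'
#' @param stream Raw stream `data.table` (see [synthesize_raw_stream()] for
#'   the schema). Calibration-line rows are ignored here; see
#'   [parse_cal_blocks()].
#' @param inlet_s,outlet_s Nominal block lengths (s), informational.
#' @param lag_s Seconds excluded at the start of every block.
#' @param min_usable_s Minimum usable averaging window (s).
#' @param r_vpdb,co2_scale Constants for the derived delta13C and total CO2
#'   (the scale factor can absorb the neglected rare-isotopologue
#'   correction, ~1.004; default 1).
#' @return A cycles `data.table`: plant_id, compartment, chamber_id, time_s
#'   (cycle start), cycle_end, averaged x626/x636/w for inlet and outlet,
#'   derived c_in/c_out/delta_in/delta_out, flow_molar, cycle-mean
#'   environment, qc_flags. Attribute `dropped` counts discarded blocks.
#' @export
parse_cycles <- function(stream, inlet_s = 134, outlet_s = 136, lag_s = 20,
                         min_usable_s = 10, r_vpdb = R_VPDB, co2_scale = 1) {
  st <- data.table::as.data.table(stream)
  need <- c("time_s", "chamber_id", "line", "x626", "x636", "w_h2o",
            "flow_lpm")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("parse_cycles: stream is missing column(s): ",
         paste(miss, collapse = ", "))
  st <- st[line %in% c("inlet", "outlet")]
  if (!nrow(st)) stop("parse_cycles: no inlet/outlet samples in stream")

  # original order within each chamber must be strictly time-increasing
  if (st[, any(diff(time_s) <= 0), by = chamber_id][, any(V1)])
    stop("parse_cycles: non-monotone timestamps within a chamber")

  period <- st[, stats::median(diff(time_s)), by = chamber_id][, min(V1)]
  gap_tol <- 3 * period
  st[, block := .block_ids(line, time_s, gap_tol), by = chamber_id]

  blocks <- st[, {
    start <- time_s[1]
    dur <- time_s[.N] - start + period
    use <- time_s - start >= lag_s
    c(list(line = line[1], start = start, end = start + dur, dur = dur,
           n_used = sum(use)),
      lapply(.SD[use], mean))
  }, by = .(chamber_id, block),
  .SDcols = intersect(c("x626", "x636", "w_h2o", "PAR", "T_air", "T_leaf",
                        "T_soil", "SMC", "RH", "flow_lpm"), names(st))]

  short <- blocks$dur < lag_s + min_usable_s
  n_short <- sum(short)
  blocks <- blocks[!short]
  data.table::setorder(blocks, chamber_id, start)

  # pair each inlet block with the immediately following outlet block of the
  # same chamber (next block, adjacent in time)
  env_cols <- intersect(c("PAR", "T_air", "T_leaf", "T_soil", "SMC", "RH",
                          "flow_lpm"), names(blocks))
  shift_cols <- c("line", "start", "end", "x626", "x636", "w_h2o", env_cols)
  blocks[, paste0("nxt_", shift_cols) :=
           data.table::shift(.SD, -1), by = chamber_id,
         .SDcols = shift_cols]
  paired <- blocks[line == "inlet" & nxt_line == "outlet" &
                     (nxt_start - end) <= gap_tol]
  pairs <- paired[, c(list(chamber_id = chamber_id, time_s = start,
                           cycle_end = nxt_end,
                           x626_in = x626, x636_in = x636, w_in = w_h2o,
                           x626_out = nxt_x626, x636_out = nxt_x636,
                           w_out = nxt_w_h2o),
                      mget(paste0("nxt_", env_cols)))]
  data.table::setnames(pairs, paste0("nxt_", env_cols), env_cols)
  n_unpaired <- nrow(blocks) - 2L * nrow(pairs)

  meta <- if (all(c("plant_id", "compartment") %in% names(st)))
    unique(st[, .(chamber_id, plant_id, compartment)])
  else st[, .(plant_id = NA_character_, compartment = NA_character_),
          by = chamber_id]
  cy <- meta[pairs, on = "chamber_id"]
  cy[, flow_molar := flow_lpm_to_mol(flow_lpm)]
  cy[, qc_flags := ""]
  .finalize_cycle_deltas(cy, r_vpdb, co2_scale)
  data.table::setorder(cy, chamber_id, time_s)
  data.table::setattr(cy, "dropped",
                      c(short = n_short, unpaired = n_unpaired))
  cy[]
}

#' Average calibration-gas blocks from a raw stream
#'
#' Extracts `line == "cal"` rows, splits them into contiguous blocks and
#' averages the isotopologue channels over each block (excluding the same
#' post-switch lag as for chamber blocks).
#'
#' @inheritParams parse_cycles
#' @return `data.table` with one row per calibration block: time_s (block
#'   midpoint), x626, x636, n. Zero rows if the stream has no cal line.
#' @export
parse_cal_blocks <- function(stream, lag_s = 20) {
  st <- data.table::as.data.table(stream)[line == "cal"]
  if (!nrow(st))
    return(data.table::data.table(time_s = numeric(), x626 = numeric(),
                                  x636 = numeric(), n = integer()))
  period <- stats::median(diff(st$time_s))
  st[, block := .block_ids(line, time_s, 3 * period)]
  st[, {
    use <- time_s - time_s[1] >= lag_s
    .(time_s = mean(time_s), x626 = mean(x626[use]),
      x636 = mean(x636[use]), n = sum(use))
  }, by = block][, block := NULL][]
}

#' Apply a two-point linear gain calibration to chamber cycles
#'
#' For every calibration block the per-isotopologue gain is the measured
#' over the assigned mole fraction of the calibration gas. Gains are linearly
#' interpolated in time between the blocks bracketing each cycle (constant
#' extrapolation at the ends) and divided out of the averaged isotopologue
#' mole fractions; the derived CO2 and delta13C columns are then recomputed.
#' With no calibration blocks the cycles pass through unchanged, with a
#' warning and a `no_calibration` QC flag.
#'
#' This linear gain/offset-free scheme is a stand-in for the instrument's
#' multi-step (dilution + span) calibration, whose internals are outside the
#' scope of this package.
#'
#' @param cycles Cycles table from [parse_cycles()].
#' @param cal Calibration blocks from [parse_cal_blocks()].
#' @param cal_co2,cal_delta Assigned composition of the calibration gas
#'   (umol mol-1, permil).
#' @inheritParams parse_cycles
#' @return The calibrated cycles `data.table` (a copy).
#' @export
apply_calibration <- function(cycles, cal, cal_co2 = 400, cal_delta = -9.5,
                              r_vpdb = R_VPDB, co2_scale = 1) {
  cy <- data.table::copy(data.table::as.data.table(cycles))
  if (is.null(cal) || nrow(cal) == 0) {
    warning("apply_calibration: no calibration blocks; identity applied")
    cy[, qc_flags := .add_flag(qc_flags, rep(TRUE, .N), "no_calibration")]
    return(cy[])
  }
  true_iso <- .to_isotopologues(cal_co2, cal_delta, r_vpdb)
  g626 <- cal$x626 / true_iso$x626
  g636 <- cal$x636 / true_iso$x636
  if (any(g626 <= 0) || any(g636 <= 0))
    stop("apply_calibration: non-positive gain")
  mid <- (cy$time_s + cy$cycle_end) / 2
  interp <- function(g) {
    if (nrow(cal) == 1) rep(g, nrow(cy))
    else stats::approx(cal$time_s, g, xout = mid, rule = 2)$y
  }
  gi626 <- interp(g626)
  gi636 <- interp(g636)
  cy[, `:=`(x626_in = x626_in / gi626, x626_out = x626_out / gi626,
            x636_in = x636_in / gi636, x636_out = x636_out / gi636)]
  .finalize_cycle_deltas(cy, r_vpdb, co2_scale)
  data.table::setattr(cy, "cal_gain_range",
                      range(c(g626, g636)))
  cy[]
}
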