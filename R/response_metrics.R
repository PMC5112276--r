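## Treatment-level aggregation and drought/recovery statistics.
##
## Conventions: the drought effect is (100 * treatment / control) - 100 (%),
## the recovery level is effect + 100, and group SDs are propagated in
## quadrature. Day/night masks follow the PAR thresholds used for reporting
## (day > 500, night < 20 umol m-2 s-1; in between is a transition excluded
## from both means).

#' Classify PAR into day, night or transition
#'
#' @param PAR Photosynthetically active radiation (umol m-2 s-1), >= 0.
#' @param day_threshold PAR above which a sample counts as day.
#' @param night_threshold PAR below which a sample counts as night.
#' @return character vector: "day", "night" or "transition".
#' @export
classify_daynight <- function(PAR, day_threshold = 500, night_threshold = 20) {
  if (any(PAR < 0, na.rm = TRUE)) stop("classify_daynight: PAR must be >= 0")
  out <- rep("transition", length(PAR))
  out[PAR > day_threshold] <- "day"
  out[PAR < night_threshold] <- "night"
  out[is.na(PAR)] <- NA_character_
  out
}

#' Aggregate per-plant flux records into treatment series
#'
#' Within each time bin, per-plant means are taken first, then the mean and
#' SD across plants. Windows: `"diurnal-day"` / `"diurnal-night"` bin by day
#' under the respective PAR mask; `"hourly"` bins by hour with no mask.
#' Points backed by fewer than `min_replicates` plants are retained but
#' marked unavailable, mirroring the display rule that at least two
#' replicates must be present.
#'
#' @param flux Flux-record table ([compute_fluxes()]) or any table with
#'   plant_id, time_s, PAR and the target variable.
#' @param variable Column name to aggregate.
#' @param window One of "diurnal-day", "diurnal-night", "hourly".
#' @param plants `data.frame` mapping plant_id to treatment.
#' @param day_threshold,night_threshold PAR mask thresholds.
#' @param min_replicates Minimum plants per point for availability.
#' @return `data.table`: variable, window, bin (day or hour index),
#'   treatment, mean, sd, n, available.
#' @export
aggregate_treatment <- function(flux, variable,
                                window = c("diurnal-day", "diurnal-night",
                                           "hourly"),
                                plants, day_threshold = 500,
                                night_threshold = 20, min_replicates = 2) {
  window <- match.arg(window)
  fx <- data.table::as.data.table(flux)
  if (!variable %in% names(fx))
    stop("aggregate_treatment: no column ", variable)
  pl <- data.table::as.data.table(plants)
  fx <- pl[fx, on = "plant_id"]
  fx[, value := get(variable)]
  if (window == "hourly") {
    fx[, bin := floor(time_s / 3600)]
  } else {
    phase <- classify_daynight(fx$PAR, day_threshold, night_threshold)
    fx <- fx[phase == if (window == "diurnal-day") "day" else "night"]
    fx[, bin := floor(time_s / 86400)]
  }
  fx <- fx[!is.na(value)]
  if (!nrow(fx))
    return(data.table::data.table(variable = character(), window = character(),
                                  bin = numeric(), treatment = character(),
                                  mean = numeric(), sd = numeric(),
                                  n = integer(), available = logical()))
  per_plant <- fx[, .(value = mean(value)), by = .(treatment, plant_id, bin)]
  out <- per_plant[, .(mean = mean(value), sd = stats::sd(value), n = .N),
                   by = .(treatment, bin)]
  out[, `:=`(variable = variable, window = window,
             available = n >= min_replicates)]
  data.table::setcolorder(out, c("variable", "window", "bin", "treatment",
                                 "mean", "sd", "n", "available"))
  data.table::setorder(out, bin, treatment)
  out[]
}

#' Propagate group standard deviations in quadrature
#'
#' sd_diff = sqrt(sd_wet^2 + sd_dry^2): the SD attached to the difference (or
#' percent effect) between the control ("wet") and drought-treated ("dry")
#' group means.
#'
#' @param sd_wet,sd_dry Non-negative group SDs.
#' @return Propagated SD.
#' @export
propagate_sd <- function(sd_wet, sd_dry) {
  if (any(sd_wet < 0 | sd_dry < 0, na.rm = TRUE))
    stop("propagate_sd: SDs must be >= 0")
  sqrt(sd_wet^2 + sd_dry^2)
}

#' Percent drought effect
#'
#' effect = 100 * treated / control - 100. Zero when the groups agree;
#' NA (with a warning) where the control mean is zero.
#'
#' @param control,treated Group means (vectors recycle).
#' @return Effect in percent.
#' @export
drought_effect <- function(control, treated) {
  bad <- control == 0
  if (any(bad, na.rm = TRUE))
    warning("drought_effect: control mean of zero; effect undefined")
  ifelse(bad, NA_real_, 100 * treated / control - 100)
}

#' Build a drought-effect series from two treatment series
#'
#' Joins control and drought aggregates by bin and attaches the percent
#' effect, the absolute propagated SD (quadrature), the same SD expressed in
#' percent of the control mean, and the recovery level (effect + 100). Bins
#' where either arm is unavailable (< 2 replicates) are marked unavailable.
#'
#' @param agg Output of [aggregate_treatment()] containing both treatments.
#' @return `data.table`: variable, window, bin, control_mean, control_sd,
#'   treated_mean, treated_sd, effect, sd_diff, sd_diff_pct, recovery_level,
#'   available.
#' @export
drought_effect_series <- function(agg) {
  ag <- data.table::as.data.table(agg)
  ctl <- ag[treatment == "control",
            .(variable, window, bin, control_mean = mean, control_sd = sd,
              control_ok = available)]
  drt <- ag[treatment == "drought",
            .(bin, treated_mean = mean, treated_sd = sd,
              treated_ok = available)]
  es <- drt[ctl, on = "bin", nomatch = NULL]
  es[, effect := drought_effect(control_mean, treated_mean)]
  es[, sd_diff := propagate_sd(control_sd, treated_sd)]
  es[, sd_diff_pct := 100 * sd_diff / abs(control_mean)]
  es[, recovery_level := effect + 100]
  es[, available := control_ok & treated_ok]
  es[, c("control_ok", "treated_ok") := NULL]
  data.table::setorder(es, bin)
  es[]
}

#' First day of recovery after re-watering
#'
#' `mode = "full"`: the first day (1-indexed from the re-watering day) on
#' which effect + sd_diff >= 0 — i.e. the recovery level plus its propagated
#' SD reaches 100 % — sustained for `consecutive` days. `mode = "level90"`:
#' the first day whose recovery level (effect + 100) reaches `level`.
#'
#' @param effect Daily percent effects, day 1 = re-watering day.
#' @param sd_diff Matching propagated SDs (percent units), used by "full".
#' @param mode "full" or "level90".
#' @param consecutive Days the criterion must hold in a row (the soil
#'   delta13C analysis uses 2).
#' @param level Recovery level threshold for "level90".
#' @return Day index, or NA if the criterion is never met.
#' @export
recovery_day <- function(effect, sd_diff = rep(0, length(effect)),
                         mode = c("full", "level90"), consecutive = 1,
                         level = 90) {
  mode <- match.arg(mode)
  stopifnot(length(sd_diff) == length(effect), consecutive >= 1)
  ok <- if (mode == "full") effect + sd_diff >= 0 else effect + 100 >= level
  ok[is.na(ok)] <- FALSE
  if (consecutive > length(ok)) return(NA_integer_)
  for (i in seq_len(length(ok) - consecutive + 1)) {
    if (all(ok[i:(i + consecutive - 1)])) return(i)
  }
  NA_integer_
}

#' Exact Wilcoxon-Mann-Whitney rank-sum test by full enumeration
#'
#' Computes the exact p-value of the rank-sum statistic by enumerating all
#' `choose(n_a + n_b, n_a)` assignments of the pooled (mid-)ranks to group A.
#' With ties, mid-ranks are assigned first and the enumeration runs over the
#' tied rank multiset. Intended for the small-sample regime (2 to 8 per
#' group) where a normal approximation is meaningless.
#'
#' Sidedness refers to group A: `"less"` tests whether A is shifted below B.
#' Under complete separation at n = 3 vs 3 the minimal attainable one-sided
#' p is 1/20 = 0.05.
#'
#' @param group_a,group_b Numeric samples, 2-8 values each.
#' @param alternative "two.sided", "less" or "greater".
#' @return list: statistic `W` (rank sum of group A), `p.value`,
#'   `alternative`, `n_assignments`.
#' @export
exact_rank_sum <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2 || n_a > 8 || n_b > 8)
    stop("exact_rank_sum: group sizes must be within 2..8 (exact ",
         "enumeration regime); use a large-sample approximation otherwise")
  r <- rank(c(group_a, group_b))  # mid-ranks under ties
  n <- n_a + n_b
  W_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(n, n_a)
  W_all <- colSums(matrix(r[combos], nrow = n_a))
  eps <- 1e-9
  p <- switch(alternative,
    less = mean(W_all <= W_obs + eps),
    greater = mean(W_all >= W_obs - eps),
    two.sided = {
      mu <- n_a * (n + 1) / 2
      mean(abs(W_all - mu) >= abs(W_obs - mu) - eps)
    })
  list(W = W_obs, p.value = p, alternative = alternative,
       n_assignments = ncol(combos))
}

#' Treatment effect via a linear mixed model with plant as random effect
#'
#' Fits `value ~ treatment` with a random intercept per plant (REML,
#' `nlme::lme`) on per-plant daily values and returns the fixed treatment
#' effect and its p-value. If the fit fails (singular or non-converging),
#' falls back to a Welch t-test on per-plant means, with a warning and
#' `method = "t.test"` in the result.
#'
#' @param data `data.frame` with columns `value`, `treatment` (two levels),
#'   `plant`.
#' @return list: `estimate` (treated minus reference level), `p.value`,
#'   `method`.
#' @export
treatment_test <- function(data) {
  d <- data.table::as.data.table(data)
  stopifnot(all(c("value", "treatment", "plant") %in% names(d)))
  d <- d[!is.na(value)]
  d[, treatment := factor(treatment)]
  if (nlevels(d$treatment) != 2)
    stop("treatment_test: exactly two treatment levels required")
  if (d[, data.table::uniqueN(plant), by = treatment][, min(V1)] < 2)
    stop("treatment_test: need >= 2 plants per treatment")
  fit <- tryCatch({
    m <- nlme::lme(value ~ treatment, random = ~ 1 | plant, data = d,
                   method = "REML")
    tt <- summary(m)$tTable
    list(estimate = unname(tt[2, "Value"]), p.value = unname(tt[2, "p-value"]),
         method = "lme")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("treatment_test: mixed model failed; falling back to t-test on ",
            "plant means")
    pm <- d[, .(value = mean(value)), by = .(plant, treatment)]
    tt <- stats::t.test(value ~ treatment, data = pm)
    fit <- list(estimate = unname(diff(rev(tt$estimate))),
                p.value = tt$p.value, method = "t.test")
  }
  fit
}

#' Repeated-measures regression of one diurnal series on another
#'
#' Fits `y ~ x` with a random intercept per plant (`nlme::lme`), e.g. the
#' delta13C of soil-respired CO2 on photosynthetic discrimination, and
#' returns the slope and its p-value.
#'
#' @param data `data.frame` with columns `x`, `y`, `plant`.
#' @return list: `slope`, `intercept`, `p.value`, `n`.
#' @export
coupling_regression <- function(data) {
  d <- data.table::as.data.table(data)
  stopifnot(all(c("x", "y", "plant") %in% names(d)))
  d <- d[stats::complete.cases(d[, .(x, y)])]
  if (nrow(d) < 3 || d[, data.table::uniqueN(paste(x, y))] < 3)
    stop("coupling_regression: need at least 3 shared time points")
  if (stats::sd(d$x) == 0)
    stop("coupling_regression: predictor is constant; slope undefined")
  m <- nlme::lme(y ~ x, random = ~ 1 | plant, data = d, method = "REML")
  tt <- summary(m)$tTable
  list(slope = unname(tt["x", "Value"]),
       intercept = unname(tt["(Intercept)", "Value"]),
       p.value = unname(tt["x", "p-value"]), n = nrow(d))
}

#' 13C enrichment of a leaf carbon fraction under drought
#'
#' Difference of group mean delta13C (treated minus control) with the
#' standard error of the difference from the group SEs in quadrature.
#'
#' @param treated,control Numeric delta13C samples (permil), or group means
#'   (then `se_treated`/`se_control` supply the printed SEs directly).
#' @param se_treated,se_control Optional group SEs; computed from the samples
#'   (sd/sqrt(n)) when omitted.
#' @return list: `difference` (permil), `se`.
#' @export
fraction_enrichment <- function(treated, control, se_treated = NULL,
                                se_control = NULL) {
  if (!length(treated) || !length(control))
    stop("fraction_enrichment: need >= 1 sample per group")
  se <- function(x, given) {
    if (!is.null(given)) given
    else if (length(x) > 1) stats::sd(x) / sqrt(length(x))
    else NA_real_
  }
  list(difference = mean(treated) - mean(control),
       se = sqrt(se(treated, se_treated)^2 + se(control, se_control)^2))
}
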