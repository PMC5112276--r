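# isochamber

Chamber-based CO₂-isotopologue flux analysis for drought and recovery
experiments on potted trees.

`isochamber` is aimed at plant ecophysiologists who run open (flow-through)
shoot/soil chamber systems coupled to an isotope laser spectrometer. A valve
system alternately feeds chamber **inlet** and **outlet** air to the
analyzer, which reports the mole fractions of the two main CO₂ isotopologues
(¹²C¹⁶O₂, ¹³C¹⁶O₂) at 0.5 Hz. The package turns those raw valve-switched
streams into:

* physiological fluxes per plant — net assimilation *A*<sub>N</sub>,
  transpiration *E*, stomatal conductance *g*<sub>s</sub>, intercellular CO₂
  (*C*<sub>i</sub>/*C*<sub>a</sub>), soil respiration *SR*;
* isotope signals — on-line photosynthetic ¹³C discrimination
  Δ¹³C<sub>obs</sub> and the δ¹³C of soil-respired CO₂;
* treatment-level statistics — percent drought effects with propagated SDs,
  recovery days after re-watering, an exact small-sample rank-sum test, and
  mixed-model treatment/coupling tests.

Because raw data of this kind are rarely deposited, the package ships a
first-class **synthetic chamber simulator**: it generates the environmental
drivers and ground-truth fluxes of a configurable control/drought experiment
(3 + 3 beech saplings by default), inverts the very mass balances the
pipeline uses to produce a realistic raw stream (valve cycles, measurement
noise, optional gain drift and calibration gas blocks), and exposes the
truth so the whole chain can be validated closed-loop: with zero noise the
pipeline recovers every prescribed quantity to ≤ 1e-6 relative error.

## The calculations

All δ values are on the V-PDB scale, δ¹³C = (R<sub>sample</sub>/R<sub>VPDB</sub> − 1),
with δ computed from cycle-averaged isotopologue mole fractions
(ratio of means).

Open-system chamber balances (flow *u* in mol s⁻¹, mole fractions *c* for
CO₂ and *w* for water vapor, leaf area *LA*, soil area *SA*):

    E  = u (w_out − w_in) / (LA (1 − w_out))
    gs = E (1 − (w_leaf + w_out)/2) / (w_leaf − w_out),  w_leaf = e_sat(T_leaf)/P
    A_N = u (c_in − c_out)/LA − E c_out
    c_i = ((g_c − E/2) c_out − A_N) / (g_c + E/2),       g_c = gs/1.6
    SR  = u (c_out − c_in) / SA

On-line discrimination, with ξ = c_in/(c_in − c_out) and δ as dimensionless
fractions:

    Δ¹³C_obs = ξ (δ_out − δ_in) / (1 + δ_out − ξ (δ_out − δ_in))

δ¹³C of soil-respired CO₂ by two-end-member isotopic mass balance:

    δ¹³C_SR = (δ_out c_out − δ_in c_in) / (c_out − c_in)

Treatment statistics: drought effect = 100·treatment/control − 100 (%);
SD_diff = √(SD_wet² + SD_dry²); full recovery on the first day (day 1 = the
re-watering day) with effect + SD_diff ≥ 0; exact Wilcoxon–Mann–Whitney p by
full enumeration of rank assignments.

## Worked example

Three simulated days: two under full drought, re-watering at 02:30 of day 2.

```r
library(isochamber)

cfg <- sim_config(seed = 7, days = 3, drought_start_day = -10,
                  rewater_day = 2, sample_period_s = 10)
sim    <- simulate_experiment(cfg)              # drivers, truth, raw stream
cycles <- parse_cycles(sim$stream)              # 134/136 s blocks, 20 s lag cut
fluxes <- compute_fluxes(cycles, leaf_area = cfg$leaf_area,
                         soil_area = cfg$soil_area)

plants <- data.frame(plant_id = c(paste0("C", 1:3), paste0("D", 1:3)),
                     treatment = rep(c("control", "drought"), each = 3))
es <- drought_effect_series(
  aggregate_treatment(fluxes, "A_N", "diurnal-day", plants))
es[, .(bin, control_mean, treated_mean, effect, sd_diff, recovery_level)]
#>      bin control_mean treated_mean effect sd_diff recovery_level
#> 1:     0         4.05         2.52 -37.90  0.0350           62.1
#> 2:     1         4.05         2.52 -37.81  0.0365           62.2
#> 3:     2         4.04         3.83  -5.35  0.0268           94.6
```

Daytime net assimilation of the drought group sits ~38 % below control while
the soil is dry and rebounds to within ~5 % of control on the re-watering
day. The same call with `"Delta13C_obs"` shows discrimination dropping from
≈ 21.5 ‰ to ≈ 13.6 ‰ under drought (−8 ‰) and recovering likewise. The exact
rank-sum test on leaf-extract δ¹³C values with complete group separation at
n = 3 vs 3 returns the minimal attainable one-sided p:

```r
exact_rank_sum(c(-28.63, -28.88, -28.38), c(-27.21, -27.29, -27.13),
               "less")$p.value
#> [1] 0.05
```

A full reproducible run from one config and seed, via the CLI dispatcher:

```r
isochamber_main(c("all", "--seed", "7", "--out-dir", "run1", "--no-plots"))
# writes raw_stream.csv, truth.csv, cycles.csv, fluxes.csv,
#        results.csv, summary_table.csv, recovery_days.csv
```

## Documentation

The methods vignette (`vignettes/isotope-flux-pipeline.Rmd`) describes the
model and its assumptions, what the simulator does and does not emulate,
all numerical choices (QC thresholds, psychrometric constants, averaging
order), and known limitations.
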