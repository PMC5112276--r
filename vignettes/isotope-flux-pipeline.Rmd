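---
title: "From raw isotopologue streams to drought-recovery metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw isotopologue streams to drought-recovery metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isochamber)
library(data.table)
```

## The measurement problem

A flow-through (open) chamber encloses the shoot or the soil of a potted
tree. Air of known composition enters at a metered flow, the enclosed
compartment adds or removes CO₂ and water vapor, and the outlet composition
is measured. A valve system alternately routes inlet air (134 s) and outlet
air (136 s) to a laser spectrometer that reports the ¹²C¹⁶O₂ and ¹³C¹⁶O₂
mole fractions at 0.5 Hz; the first 20 s after each valve switch are
discarded as flushing lag. One inlet block plus the following outlet block
of the same chamber form a *cycle*, the atomic unit from which all fluxes
are computed.

Two isotope quantities carry the biology. On-line photosynthetic
discrimination Δ¹³C\_obs measures how strongly Rubisco's preference for
¹²C is expressed, which scales with the ratio of intercellular to ambient
CO₂ (C\_i/C\_a) and therefore closes down under drought (stomata shut,
C\_i falls, Δ drops). The δ¹³C of soil-respired CO₂, obtained from a
two-end-member mass balance on the soil chamber, carries a damped, lagged
imprint of that aboveground signal when root respiration is fed by recent
photoassimilates — the coupling this pipeline is designed to quantify.

## Model and assumptions

With molar flow $u$ (converted from l min⁻¹ at 298.15 K and 1013.25 hPa,
since chamber flows are metered volumetrically), water vapor mole fractions
$w$, CO₂ mole fractions $c$ (µmol mol⁻¹), leaf area $LA$ and soil area
$SA$:

$$E = \frac{u\,(w_{out}-w_{in})}{LA\,(1-w_{out})}, \qquad
g_s = \frac{E\,\bigl(1-(w_{leaf}+w_{out})/2\bigr)}{w_{leaf}-w_{out}}$$

$$A_N = \frac{u\,(c_{in}-c_{out})}{LA} - E\,c_{out}, \qquad
c_i = \frac{(g_c - E/2)\,c_{out} - A_N}{g_c + E/2},\; g_c = g_s/1.6$$

$$SR = \frac{u\,(c_{out}-c_{in})}{SA}$$

$$\Delta^{13}C_{obs} =
\frac{\xi(\delta_{out}-\delta_{in})}{1+\delta_{out}-\xi(\delta_{out}-\delta_{in})},
\quad \xi = \frac{c_{in}}{c_{in}-c_{out}}, \qquad
\delta^{13}C_{SR} =
\frac{\delta_{out}c_{out}-\delta_{in}c_{in}}{c_{out}-c_{in}}$$

Assumptions worth stating explicitly:

* **δ in fractional units inside Δ.** The $1+\delta_{out}$ term is only
  dimensionally consistent when δ is a dimensionless fraction; the API takes
  and returns ‰ and converts internally.
* **Boundary-layer resistance neglected.** Shoot chambers are fan-stirred;
  $w_{leaf}=e_{sat}(T_{leaf})/P$ is taken as saturated at leaf temperature.
* **Wet mole fractions.** CO₂ is used as measured; an optional dry-air
  correction $c/(1-w)$ exists (`dry_correction`) but is off by default
  because the reference workflow does not state one.
* **Total CO₂ = x626 + x636.** Rarer isotopologues are neglected; the
  omission is a near-constant ≈1.004 factor that cancels in concentration
  differences. A configurable `co2_scale` can absorb it.
* **No mesophyll-conductance or ternary corrections** to discrimination; no
  leaf energy balance (leaf temperature is a measured input).

## Key parameters

| Parameter | Default | Why |
|---|---|---|
| valve blocks | 134 s inlet / 136 s outlet | instrument schedule of the emulated system |
| post-switch lag | 20 s | tubing/cell flushing after valve switching |
| minimum usable window | lag + 10 s | below this a block mean is meaningless; block dropped with QC flag |
| QC threshold on $|c_{in}-c_{out}|$ | 5 µmol mol⁻¹ | guards the ξ and mass-balance divisions at dawn/dusk; undocumented upstream, chosen here |
| day / night PAR masks | > 500 / < 20 µmol m⁻² s⁻¹ | the reporting convention for daytime and nighttime means; Δ¹³C\_obs is only reported under the day mask |
| R_VPDB | 0.0111802 | a fixed published convention; configurable everywhere |
| Magnus $e_{sat}$ | 6.112·exp(17.62 T/(243.12+T)) hPa | a standard psychrometric form; the upstream formula is unstated |

## What the simulator emulates

The generator's defaults *are* the stated world of the emulated experiment:
3 control + 3 drought-treated saplings; a 16/8 h photoperiod with a 3 h
linear ramp up and 5 h ramp down to a 600 µmol m⁻² s⁻¹ plateau (lights
07:00–23:00, plateau 10:00–18:00); drought-arm soil moisture declining
from 31 % to 24.1 % over 8 days and re-watering to 33 % at 02:30 of the
re-watering day; daytime VPD 8.7 hPa (control) rising toward 17.1 hPa at
full drought; air 25.4/17.2 °C day/night with a small drought warming;
leaf 0.8 °C below air; soil ≈16.7 °C; δ¹³C measurement noise consistent
with a 0.25 ‰ Allan deviation at 1 s.

Physiology is deliberately minimal and monotone:
$g_s = g_{s,max} f_{SMC} f_{VPD} f_{PAR}$ with a hyperbolic VPD response
(half-saturation 15 hPa), a linear soil-moisture response closing at 20 %
SMC, and a saturating light response; $A_N$ is the unique positive root of
supply $= (g_s/1.6)(c_a - c_i)$ against a Michaelis-type demand
$a_{max}L(PAR)\,c_i/(c_i+K)$, solved jointly with the chamber CO₂ balance
so that $c_a$ *is* the chamber (outlet) concentration; truth discrimination
is $a + (b-a)\,c_i/c_a$ with $a = 4.4$ ‰ (diffusion) and $b = 30$ ‰
(carboxylation); soil respiration has a Q₁₀ = 2 temperature response around
16.7 °C and a linear soil-moisture response. Those few constants were fixed
once so that the *stated* daytime contrasts emerge: discrimination drops by
≈8 ‰ and the fluxes by roughly a third to a half at full drought. With a
coupling damping $k = 0.15$ the soil-respired δ¹³C then rises by ≈1.2 ‰,
inside the stated 1–1.5 ‰ band.

The δ¹³C\_SR coupling,
$\delta_{SR}(t) = \delta_{SR,base} - k\,(\Delta(t-lag) - \bar\Delta_{baseline})$,
is a *descriptive* damped-lag model. The upstream work does not state the
damping or the lag; $k$ and the 4 h default lag were chosen to reproduce the
printed ≈8 ‰ aboveground vs ≈1–1.5 ‰ belowground contrast and are not
asserted as mechanism.

Choices made where the record is silent: ambient (inlet) CO₂ 420 µmol mol⁻¹
at −9.3 ‰ (slightly CO₂-enriched indoor air); nighttime VPD 4 hPa; dark
shoot respiration 0.5 µmol m⁻² s⁻¹ of −26.5 ‰ CO₂; leaf area 0.15 m² and
soil area 0.045 m² (0.8 m saplings in 7.9 l pots); shoot/soil flows 14 and
2.2 l min⁻¹ (mid-range of the stated bands); lognormal 3 % plant-to-plant
scatter on $g_{s,max}$ and the soil respiration base (consistent with the
small printed between-plant SDs); the analyzer visits the 12 chambers
round-robin, one cycle each (≈54 min revisit, matching the hourly
resolution of the reference system).

**What the simulator does not emulate** — and hence what a green
closed-loop test does not establish: transpiration feedback on chamber
humidity (VPD is a prescribed driver, as in the reference analysis, not a
solved state); drift spectra (noise is white Gaussian scaled by
$1/\sqrt{\tau}$, anchored only at the printed Allan point); soil microbial
carbon pools or any mechanistic route from assimilate transport to root
respiration; the ¹²C¹⁶O¹⁸O channel; real instrument calibration chemistry.
Closed-loop recovery to 1e-6 demonstrates that the pipeline inverts its own
mass balances exactly and propagates no unit errors — it cannot validate
the physiological realism of the generator itself.

## Numerical and procedural choices

* **Averaging order.** δ is computed from cycle-averaged isotopologue mole
  fractions (ratio of means), which is less noise-biased than averaging
  per-sample ratios; the two orders agree to ≤0.01 ‰ at realistic noise
  (tested).
* **Calibration.** A two-point linear per-isotopologue gain, interpolated in
  time between hourly calibration-gas blocks, is a documented stand-in for
  the instrument's multi-step dilution/span calibration. It corrects an
  injected 10⁻³ linear gain drift to ≤0.05 ‰. Without calibration blocks the
  identity is applied with a warning and QC flag.
* **Recovery criterion.** "Mean drought effect plus standard deviation
  exceeded 100 %" is implemented as recovery level (effect + 100) plus the
  propagated SD reaching 100 %, i.e. effect + SD ≥ 0. Read literally the
  phrase is self-inconsistent (the effect is ≈0, not ≈100, at recovery);
  this reading reproduces the reported usage. Day 1 is the re-watering day;
  the soil-δ¹³C analysis requires the criterion to hold 2 consecutive days.
  The 90 % level is a configurable threshold on effect + 100; the published
  2.75 ‰ operationalization for discrimination does not follow transparently
  from 90 % of any printed mean and is left configurable, not resolved.
* **Rank-sum sidedness.** The printed leaf-fraction p = 0.050 at n = 3 vs 3
  equals the minimal attainable *one-sided* exact p (1/20); both sidedness
  options are exposed and the two.sided default is conservative.
* **Mixed models.** Treatment and coupling tests are thin contracts over
  `nlme::lme` (random intercept per plant), matching the reference
  workflow's use of an off-the-shelf routine; a singular fit falls back to a
  t-test on plant means with a warning. The package validates interface
  behavior (type-I calibration, power, slope recovery) rather than the
  likelihood internals.
* **Machine vs display precision.** `raw_stream.csv`, `truth.csv`,
  `cycles.csv` and `fluxes.csv` are written at full precision so that
  downstream closed-loop guarantees survive a file round-trip; only the
  human-readable `summary_table.csv` applies the reporting precision
  (fluxes 2–3 d.p., δ/Δ 2 d.p., effects 1 d.p.).
* **Run length.** `rewater_day = days` is allowed and means the run ends
  before re-watering; it is how short all-drought validation runs are
  expressed.
* **Soil moisture trajectory.** The draw-down reaches its minimum over a
  fixed number of days (default 8) and then holds until re-watering, so
  that the main drought window is at full intensity — the printed drought
  window reports soil moisture already at its minimum.

## Known limitations

* The supply/demand closure cannot simultaneously reproduce every printed
  absolute mean (e.g. control Δ¹³C\_obs ≈ 21.5 ‰ in the simulator vs a
  printed 24.9 ‰) while honoring the printed conductances and drawdowns;
  the *contrasts* (the ≈8 ‰ drop, the percent effects) are the calibration
  anchors, and the recovery-of-parameters tests compare against the
  simulator's own prescribed truth, never against printed absolutes.
* The exact rank-sum test enumerates up to n = 8 per group and deliberately
  refuses larger samples rather than silently approximating.
* `parse_cycles` assumes each chamber's samples are time-ordered and treats
  gaps > 3 sampling periods as block boundaries; irregular multiplexing
  schedules are handled, overlapping duplicate timestamps are a hard error.
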