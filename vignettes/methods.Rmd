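---
title: "Methods: design of the bloomflux analysis chain and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design of the bloomflux analysis chain and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific question

In mid-latitude seas such as the Northwestern Mediterranean, the surface
chlorophyll record between January and April is not a smooth ramp into the
spring bloom: it fluctuates on 8-day-to-monthly scales. The working
hypothesis implemented here is that these subseasonal fluctuations are
driven by atmospheric modulations of upper-ocean vertical stability.
While the net air-sea heat flux (NHF) is negative, the surface loses
buoyancy, convection stirs the upper layer, and each storm both deepens
the actively mixing layer (diluting surface chlorophyll by entrainment)
and recharges surface nutrients; in the calm, warming spells between
storms the layer restratifies and surface biomass rebounds. Once the NHF
switches durably to positive — convection shutdown — stability is no
longer interrupted, the surface bloom develops, and thereafter grazing
and nutrient drawdown take over, so the same stability fluctuations no
longer produce growth responses of the same sign.

Three statistics carry the test:

1. **Sign agreement** between the 8-day change in a stability driver
   (d(NHF)/dt, or -d(WS)/dt for wind stress) and the net growth rate
   r = d ln(SChl)/dt. Under the stability hypothesis, agreement should
   be well above 50% while convection is active (January-February) and
   drop toward chance after stratification (March-April).
2. A **lag composite** of r about the last persistent
   negative-to-positive NHF zero-crossing of each year: growth should
   peak at lag 0, the interval spanning the shutdown itself.
3. **Binned growth-stability relations** by stability regime: intervals
   are classified from the NHF signs at their endpoints into
   winter-unstable (-,-), transition shutdown (-,+), transition resume
   (+,-) and spring-stable (+,+), and r is bin-averaged against
   d(NHF)/dt within each class.

## Core definitions

All series live on the standard 8-day ocean-colour compositing calendar:
windows anchored to January 1 of each year, 46 per year, the last one
truncated at December 31. For a window series `x[t]`:

* net growth rate: `r[t] = (ln SChl[t+1] - ln SChl[t]) / 8` (day^-1),
  assigned to the interval starting at `t`;
* driver derivative: `(x[t+1] - x[t]) / 8`;
* NHF = shortwave + longwave + latent + sensible (W m^-2, positive into
  the ocean); wind stress `tau = rho_air c_d (u10^2 + v10^2)` with
  `rho_air = 1.22 kg m^-3`, `c_d = 1.3e-3`;
* zero is counted as *stable* (NHF = 0 means buoyancy loss has ceased);
* the event-analysis window is January 1 - April 30 (window centers up
  to day of year 120/121); a negative-to-positive crossing is
  *persistent* when NHF stays nonnegative through that window;
* seasons are by window-center month: winter = Jan-Feb,
  spring = Mar-Apr; a derivative interval takes the season of its first
  window.

## The X-11 style decomposition

Intraseasonal variability (ISV) is isolated with an additive Census
X-11 style scheme (`x11_decompose()`), period `p = 46`:

1. initial trend `T1` = centered 2xp moving average (p+1 points, end
   weights 1/(2p), interior 1/p);
2. detrend `Z = X - T1`;
3. seasonal estimate: each of the p phases is smoothed across years
   with the 3x3 composite filter (1,2,3,2,1)/9, and the result is
   centered by subtracting its own 2xp moving average, giving `S1`;
4. refined trend `T2` = 23-point Henderson low-pass of `X - S1` (the
   Henderson weights come from the closed-form polynomial formula and
   are validated against the published 13-term filter);
5. the seasonal pass is repeated against `T2`, giving the final `S`;
   the final trend is the Henderson filter of `X - S` and the irregular
   is the exact residual `I = X - T - S`.

Design choices worth noting:

* **Additive, on SChl directly.** Growth rates are handled separately
  in log space, so the decomposition itself stays additive and exactly
  reconstructive.
* **End effects.** At series ends (and next to masked values) every
  kernel is truncated to the available points and renormalized, rather
  than using the classical asymmetric X-11 end weights; this keeps the
  filters linear, mask-aware and easy to test.
* **What "irregular" means here.** With a 23-term (~6-month) Henderson
  trend and the 3x3 seasonal filter, `I` contains sub-six-month,
  non-seasonal variability — the intraseasonal band of interest.
* **Known variance budget.** Because the 3x3 seasonal filter has
  center weight 1/3 and the Henderson center weight is 0.144, white
  noise leaves roughly 44% of its variance in `I` (the dominant single
  share, but far from all of it); a stronger separation would need the
  longer 3x5 seasonal filter. The test suite pins the behaviour actually
  delivered.

The ISV intensity maps normalize the seasonal (population) standard
deviation of `I` by that pixel's seasonal-mean SChl.

## The synthetic dataset

Real ocean-colour and reanalysis archives cannot ship with a package,
so the chain is validated on a simulator whose mechanisms are known by
construction (`sim_config()`, `simulate_dataset()`). The defaults *are*
the study conditions: they were fixed once, by design-time calibration
against the qualitative phenomenology above, and are not tuned per run.

**Forcing.** NHF follows a seasonal sine with amplitude 200 W m^-2
crossing zero upward at day 74 (mid-March). Storms are one-window
Bernoulli events whose probability ramps from 0.05 in summer to 0.25 at
the mid-February peak; each adds a lognormal wind-stress anomaly (mean
0.15 N m^-2) and removes 800 W m^-2 per unit anomaly from the NHF —
the latent/sensible response that makes d(NHF)/dt and d(WS)/dt strongly
anti-correlated (about -0.86 at the defaults), as both derive from the
same storm systems. Calm-weather wind stress is lognormal jitter around
0.05 N m^-2; NHF carries 15 W m^-2 Gaussian noise.

**Ocean.** A slab "actively mixing layer" of depth `h` relaxes toward a
target `h* = h_min + 0.45 * max(0, -NHF_eff)` (clamped to 15-500 m),
where `NHF_eff` blends the instantaneous NHF (weight 0.6) with a 40-day
low-pass that stands in for the convective preconditioning of the water
column. Deepening is fast (2-day e-folding) and entrains deep water
(0.05 mg Chl m^-3, full nutrients), diluting the surface by exact
inventory conservation (`entrain_dilute()`); restratification is slow
(10 days). Phytoplankton grow at
`mu = mu_max * Ibar/(K_I + Ibar) * N/(K_N + N)` with depth-averaged
irradiance `Ibar = I0 (1 - exp(-k h))/(k h)`, and lose biomass to a
constant background (0.1 day^-1) plus grazing whose pressure tracks
food with an 8-day rise and 15-day decay — the lag that lets the bloom
overshoot and then decay through spring. The nutrient pool is drawn
down by production and recharged in proportion to mixed-layer depth.
The 8-day forcing step is integrated with daily biological substeps to
avoid discrete-map overshoot. Observed SChl adds independent
multiplicative lognormal noise (sigma = 0.1) per pixel; on grids, a
per-pixel multiplier on `mu_max` (default a 0.4-1.15 longitude
gradient) emulates the onshore-offshore productivity gradient so that a
bloom mask with the 0.65 mg m^-3 spring-climatology threshold selects a
nontrivial region.

**What the simulator does and does not claim.** It reproduces the
mechanism chain (storm -> mixing -> dilution + light loss; calm ->
restratification -> rebound; shutdown -> bloom; grazing/nutrients ->
spring decay) and the qualitative statistics built on it. It does not
emulate advection, eddy restratification, subsurface structure,
realistic cloud/irradiance series, or observational coverage gaps, and
its headline percentages are not expected to match satellite values
numerically.

## Problem sizes

The default study uses a 50-year single-pixel record for time-series
statistics (about 47 persistent shutdown events — enough for stable
composite means) and a 20-year 2x6-pixel grid for the maps. Both run in
seconds; sizes are a package choice balancing statistical stability
against test runtime, not an emulation of any particular archive.

## Numerical choices

* growth intervals touching masked or non-positive SChl are masked, and
  non-positive unmasked SChl is an error naming the offending step;
* sign-agreement counts exclude exactly-zero growth or driver values
  from numerator and denominator (zeros are sign-ambiguous) and require
  5 countable intervals per pixel-season;
* driver bins default to 9 equal widths over the central 98% of driver
  values with a 10-interval reliability floor; a zero-spread driver
  (noise-free runs) collapses to one narrow bin;
* composite lags run -24 d to +24 d in 8-day steps; the lag-0 interval
  spans the crossing; lags reaching before the analysis window are
  recorded missing rather than borrowed from the previous year;
* all file outputs are deterministic given the seed, and the pipeline
  manifest checksums every artifact so reruns can be compared
  byte-for-byte.
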