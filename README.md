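# bloomflux

Subseasonal surface-chlorophyll fluctuations and the air-sea forcing of
the winter-spring bloom.

In mid-latitude seas the January-April surface chlorophyll (SChl) record
fluctuates on 8-day-to-monthly scales on its way into the spring bloom.
`bloomflux` implements an analysis chain for the hypothesis that these
fluctuations are driven by atmospheric modulations of upper-ocean
vertical stability: storms and surface cooling (negative net heat flux,
NHF) deepen the actively mixing layer, diluting surface chlorophyll and
recharging nutrients; calm warming spells restratify it and let biomass
rebound; and the bloom proper starts when the NHF switches durably from
negative to positive — convection shutdown — after which grazing and
nutrient drawdown, not stability, control the signal.

The package provides:

* **metrics** — NHF assembly (shortwave + longwave + latent + sensible),
  bulk wind stress `tau = rho_air c_d (u^2 + v^2)`, the log-scale net
  growth rate `r = d ln(SChl)/dt` (day^-1) on 8-day intervals, forward
  derivatives, and season masks (winter = Jan-Feb, spring = Mar-Apr);
* **decomposition** — an additive Census X-11 style scheme (2x46 moving
  average, per-phase 3x3 seasonal filter, 23-term Henderson trend) that
  reconstructs exactly and isolates intraseasonal variability (ISV),
  plus normalized ISV-intensity maps;
* **events** — NHF-sign regime classification per interval
  ((-,-) winter-unstable, (-,+) shutdown, (+,-) resume, (+,+)
  spring-stable), zero-crossing detection in the January 1 - April 30
  window with persistence flags, lag composites of growth about the
  last persistent shutdown (-24 d to +24 d), and bin-averaged
  growth-vs-d(NHF)/dt relations per regime;
* **maps** — seasonal climatologies, the bloom-region mask
  (climatological spring SChl > 0.65 mg m^-3), and sign-agreement
  percentage maps between driver derivatives and growth;
* **grid_io** — 8-day compositing calendar, daily-to-8-day aggregation,
  bilinear regridding, box means, and NetCDF/CSV round-trip I/O;
* **synthetic_data** — a stochastic storm-forcing + slab mixed-layer
  phytoplankton simulator whose mechanisms are known by construction,
  used to validate the whole chain end to end (see the methods
  vignette, `vignettes/methods.Rmd`);
* **pipeline** — `run_full_analysis()`, a one-call orchestration that
  writes every artifact with a checksummed JSON manifest,
  deterministically in the seed.

## Worked example

Fifty years of synthetic data at one pixel, then the three headline
statistics:

```r
library(bloomflux)

b  <- simulate_dataset(sim_config(n_years = 50, seed = 42))
px <- bundle_pixel(b)           # date, schl, nhf, ws
ax <- b$schl$axis

r    <- net_growth_rate(px$schl)       # day^-1, one value per interval
dnhf <- forward_derivative(px$nhf)     # W m^-2 day^-1

## 1. Sign agreement, winter vs spring
g <- array(r, c(ax$n_steps - 1, 1, 1))
d <- array(dnhf, c(ax$n_steps - 1, 1, 1))
sign_agreement_map(g, d, ax, "winter", "nhf", 41.5, 4)$values[1, 1, 1]
#> [1] 72.57143
sign_agreement_map(g, d, ax, "spring", "nhf", 41.5, 4)$values[1, 1, 1]
#> [1] 59.5
## winter agreement well above chance; spring much closer to it

## 2. Growth composited about convection shutdown
ev <- find_zero_crossings(px$nhf, ax)
sum(ev$persistent)
#> [1] 47
composite_about_crossing(r, ev, ax)
#>   lag_days         mean         sd  n
#> 1      -24  0.022313754 0.04373426 47
#> 2      -16  0.025517421 0.02795852 47
#> 3       -8  0.005267416 0.04685864 47
#> 4        0  0.034277741 0.02576904 47
#> 5        8  0.027382098 0.03332164 47
#> 6       16 -0.007677268 0.02344589 47
#> 7       24 -0.017608912 0.02473745 47
## mean growth peaks at lag 0, the interval spanning the shutdown

## 3. The two drivers come from the same storms
cor(dnhf, forward_derivative(px$ws))
#> [1] -0.8612803
```

On a grid, the onshore-offshore productivity gradient gives a
nontrivial bloom region, and winter agreement beats spring over it:

```r
bg   <- simulate_dataset(sim_config(n_years = 20, seed = 42,
                                    n_lat = 2, n_lon = 6))
mask <- bloom_mask(seasonal_climatology(bg$schl, "spring"))
sum(mask)
#> [1] 6
## bloom-region means, NHF driver: winter 77.6 %, spring 50.8 %
```

## Data model

All computation runs on a `forcing_bundle`: three `grid_field`s (`schl`,
`nhf`, `ws`) sharing one regular lat/lon grid and one 8-day `time_axis`
(windows anchored to January 1, 46 per year, final window truncated).
`write_bundle()`/`read_bundle()` round-trip bundles through NetCDF;
`write_pixel_csv()`/`read_pixel_csv()` do the same for single-pixel
series; real gridded data can enter through `aggregate_time_8day()` and
`regrid_bilinear()`.
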