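---
title: "Methods: climate-change impacts along the arctic tern Atlantic flyway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-change impacts along the arctic tern Atlantic flyway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternwinds)
```

## The problem

Arctic terns (*Sterna paradisaea*) migrate annually between Arctic breeding
colonies and the Antarctic pack-ice zone, the longest migration of any
animal. Along the Atlantic/Indian Ocean flyway they depend on three
environmental systems that climate change is reshaping: net primary
production (NPP) at a handful of stopover foraging regions, the Southern
Ocean sea-ice edge where they rest and forage in austral summer, and the
prevailing winds that subsidise their flight. `ternwinds` implements the
analysis chain needed to quantify end-of-century change in each system and
to propagate wind change into migration consequences, exercisable end to
end on a bundled synthetic-climate generator.

All gridded analysis happens on a regular 1° latitude-longitude grid of
cell centres at the half degrees, on a 365-day (no-leap) calendar — the
common denominator of regridded Earth-system-model output. Because no
NetCDF reader is a dependency of this package, gridded fields are
exchanged as long-format CSV with a metadata header
(`write_grid_csv()`/`read_grid_csv()`); the in-memory `grid_field`
container is the interface every analysis function consumes.

## Tern-day density and regional weighting

Tracking fixes (GPS at 18-h nominal intervals; light-level geolocators at
~daily intervals with ~185 km accuracy and equinox gaps) are binned to 1°
cells as *tern-days*: each fix contributes the elapsed time to the bird's
next fix, assigned to the fix's cell, and the final fix contributes one
nominal interval. Two conventions deserve making explicit because the
underlying idea ("total time spent per cell") does not fix them:

* **Gap handling.** Intervals longer than twice the device's nominal
  interval (equinox gaps, 24-h daylight) are capped at that bound rather
  than interpolated — interpolation would invent positions no device
  recorded.
* **Cell membership.** A fix belongs to the half-open cell
  `[i, i+1) × [j, j+1)` containing it.

The surface is smoothed with a truncated Gaussian kernel (radius 4σ,
default σ = 1 cell, configurable since the bandwidth is a free choice).
Smoothing is implemented as mass redistribution with per-source
renormalisation at grid edges, so the global tern-day total is conserved
exactly; the price is that a uniform field is an eigenfunction of the
smoother only beyond two kernel radii from the grid edge (the two
properties are mutually exclusive at edges, and conservation is the one
the downstream weighting relies on).

Regional weights divide each cell's tern-days by the regional total over
one of the four key boxes — North Atlantic subpolar gyre (40–65° N,
60° W–0°), Benguela upwelling (40° S–0°, 10° W–30° E), Subantarctic Indian
Ocean (55–20° S, 50–100° E), Southern Ocean (poleward of 55° S) — so that
regional NPP reflects the cells terns actually use. A region with no
tracked occupancy falls back to uniform weights with a warning.

## NPP emergence statistics

Ensemble post-processing is deliberately plain: unweighted cellwise
multi-model means (missing cells ignored pairwise), period means over
1850–1950 (preindustrial baseline), 1995–2014 (present day) and 2081–2100
(end of century), percent change relative to the baseline with
near-zero-baseline cells masked, and a model-agreement mask flagging cells
where at least 75 % of members (9 of 12) share the sign of change; members
with exactly zero change count toward neither sign.

Two signal-to-noise statistics decide when change *emerges* from
variability, both reported against a ±1 "normal" envelope:

* **Sensitive** (no adaptation): the signal in year *y* is the decadally
  smoothed weighted regional series minus the 1850–1950 mean; the noise is
  one SD of interannual variability. Decadal smoothing is a 10-year
  centred running mean, truncated at the series edges (an even window
  takes 4 years before and 5 after). S:N beyond ±1 means conditions
  outside the envelope the population is adapted to; the sign follows the
  trend.
* **Conservative** (full generational adaptation): for each fledging year,
  the signal is the least-squares trend over a 15-year lifespan times
  14 years (the total change a bird experiences), the noise the population
  SD of the same window, and the window is reported against its start
  year. On a noiseless ramp this equals `14/sqrt((15²−1)/12) ≈ 3.2404`
  regardless of slope, because the statistic reduces to 3.2404 times the
  window's correlation with time. That identity also gives its null
  calibration in closed form: under white noise `P(|S:N| > 1) ≈ 0.263`
  (a t₁₃ tail), i.e. the conservative statistic is intentionally noisy at
  the single-window level and only sustained multi-decadal trends produce
  persistent emergence.

Three deliberate choices, configurable where stated: the noise SD is the
population SD of *raw* (not detrended) values — detrending is available
via `detrend_noise`; and in the full regional pipeline (`regional_sn()`)
the sensitive-mode noise defaults to the ensemble mean of per-member
baseline SDs rather than the SD of the multi-model-mean series. Averaging
N members suppresses internal variability by about 1/√N, so the
multi-model-mean SD understates the variability any real bird experiences
and would make emergence look earlier and the trendless null
over-dispersed; member-based noise keeps the null quiet (max |S:N| ≈ 0.4
on synthetic trendless ensembles) while leaving the forced signal
untouched. `noise_source = "series"` restores the literal single-series
definition.

## Sea-ice edge

The ice *edge* is the 15 %-concentration contour, implemented per 1°
longitude column as the first threshold crossing scanned from the north,
linearly interpolated between the bracketing cells; concentrations exactly
at the threshold belong to ice. A per-longitude edge function is robust to
interior polynyas, which a full 2-D contour would wrap around. Decadal
climatologies average the concentration field over the decade's instances
of each month and then extract the edge (mean-then-edge); the alternative
edge-of-each-year-then-mean differs when retreat interacts with the
profile shape, and the implemented order is pinned by a regression test on
a linearly retreating field. Productivity "at the edge" is sampled as the
mean NPP within ±2° latitude of the edge per longitude across the
60° W–120° E sector, then averaged over longitudes — the band half-width
is an explicit stand-in for a sampling the source analyses leave
unspecified, and is configurable. Tracking fixes are related to the edge
by the great-circle distance to the same-longitude edge latitude.

## Wind climatology

Winds are summarised per migration phase — breeding May–August, southbound
August–October, overwinter November–March (cross-year windows labelled by
the January year), northbound April–May — as multi-model means over the
phase months and a period (historical 1960–2014, future 2080–2099),
differenced future-minus-historical, and collapsed to zonal-mean profiles.
Profiles average along each latitude without cosine weighting: each value
describes conditions along its own constant latitude rather than an area
integral.

## The vTern simulator

Virtual terns isolate the effect of wind on the northbound migration.
Each vTern is released at 70° S (2000 per release day at longitudes
equally spaced, endpoints inclusive, across 60–40° W; days 80, 90 and 100
of the year; 6000 per year), flies at a constant 10 m s⁻¹ airspeed toward
Iceland (65° N, 20° W) during the first 14 h of each UTC day, is advected
by the daily 10-m wind while flying, and is frozen — neither flying nor
drifting — during the remaining 10 h. Integration is forward Euler on a
sphere (R = 6371 km) at 1-h steps: ground velocity = wind + airspeed along
the current great-circle initial bearing to the target, Δlat = v·dt/R,
Δlon = u·dt/(R·cos lat), longitude wrapped. Crossing 60° N ends a
migration (arrival); 120 days without arrival flags failure (no cap is
inherent to the formulation, so the cap is explicit and failures are
reported separately); |lat| ≥ 89.5° aborts a trajectory because the
lon-lat metric degenerates. Wind is sampled bilinearly in space and
nearest-day in time, and a gap in the forcing is an error naming the
missing date, never silent extrapolation in time.

Choices the formulation leaves open, decided here: the bearing is
recomputed every step (a rhumb-line mode exists for sensitivity tests);
the activity clock runs in UTC from 00:00 of the release day; land does
not block movement (vTerns can and do overfly Africa); positions are
recorded every 2 h and that same sampling defines occupancy and
land-crossing tests, so a cell transited entirely between records is not
counted — a known discretisation. Land itself is a deliberately coarse 1°
mask built from hand-digitised continental outlines plus a rule-based
Antarctica; it resolves continents, not coastlines, which is sufficient
for the Africa-crossing flag (box 20° W–52° E, 35° S–38° N intersected
with the mask).

Useful exact properties follow from the construction and are enforced by
tests: with zero wind the duration matches the great-circle distance at
504 km per day of flight (14 h × 36 km h⁻¹); with the airspeed forced to
zero, drift per active hour is exactly the wind vector; duration decreases
strictly under a uniform along-track tailwind; and released = arrived +
failed + aborted always. One numerical subtlety: duration as a function of
distance is discontinuous at whole-flight-day boundaries (a 10-h overnight
rest separates finishing "tonight" from "tomorrow morning"), so oracle
comparisons are made on the continuous flight-hours scale.

## The synthetic-climate generator

The generator produces fields with the statistical structure the analyses
assume, not model physics: zonal wind as a sum of Gaussian-in-latitude
jets (Southern Ocean westerlies, Antarctic coastal easterlies, trade
belts, northern westerlies) with linear-in-time trends in peak speed and
core latitude; meridional wind as Gaussian circulation cells; a
multi-model NPP ensemble in which every member shares a forced signal
(regional baseline, flat through 2014, ramping linearly to its full
amplitude at 2081 so the prescribed fractional change equals the
2081–2100 mean relative to 1850–1950 by construction) plus a model offset
and AR(1) interannual noise; monthly sea-ice concentration as a logistic
function of latitude around a seasonally cycling, linearly retreating edge
whose exact threshold latitude is available analytically
(`analytic_ice_edge()`) as a construction oracle; and tracking fixes
interpolated along a coarse Atlantic-flyway waypoint route with stopover
dwells, device-specific intervals and noise, and optional equinox gaps.

Interannual noise is AR(1) with lag-1 correlation 0.3 by default (climate
noise is autocorrelated; zero recovers white noise), applied as one
regionally coherent series per ensemble member — real variability is
spatially correlated, and a spatially coherent term is what survives
regional averaging; optional per-cell white noise (`cell_sd`) adds
incoherent texture. Default magnitudes are chosen at realistic scales for
tern-relevant regions: baselines 0.3–0.8 g C m⁻² day⁻¹, interannual SD
0.02 g C m⁻² day⁻¹ (a few percent of the mean), inter-model offsets
0.05 g C m⁻² day⁻¹, a −50 % end-of-century North Atlantic decline under
strong forcing (halved under moderate forcing), westerlies strengthening
2.5 m s⁻¹ per century with a 3° poleward contraction, and a sea-ice edge
near 62° S ± 6° seasonally, retreating 5° per century. Every generator is
a pure function of its config and seed.

What the generator does *not* emulate — storm systems, ocean currents,
zonal wind asymmetry, spatially structured model disagreement — bounds
what passing tests show: they validate the estimators and the simulator,
not the realism of any particular climate trajectory. In particular,
synthetic-wind vTern cohorts produce tight duration spreads and (with
zonally uniform jets) essentially no Africa crossings; reproducing
tracked-tern route statistics requires real reanalysis or CMIP6 winds,
which are deliberately outside this package's scope.

## Problem sizes and numerics

The test-suite and acceptance computations run at desk scale by choice:
emergence replicate studies use the North Atlantic box (25 × 60 cells,
251 years, 12 members, 50 replicates per arm), vTern oracle cohorts use
100 releases on one day, and synthetic-wind cohorts 300 vTerns over an
Atlantic domain at daily resolution. Tolerances: edge interpolation is
exact on piecewise-linear profiles; trend recoveries are asserted within
3 standard errors or the stated band (±0.3 m s⁻¹ per century for jets,
±0.5° per century for ice retreat); Euler integration error on zero-wind
paths measures ≈ 0.1–0.25 % in flight-hours. Degenerate inputs error
loudly: zero-variance baselines and zero-variance windows with non-zero
trend refuse to divide, empty period selections and empty region
intersections are rejected.
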