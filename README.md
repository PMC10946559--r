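# ternwinds

Climate-change impacts along the arctic tern Atlantic flyway.

Arctic terns (*Sterna paradisaea*) fly between both polar regions every
year — the longest migration of any animal — and depend on productive
foraging regions en route, on the Southern Ocean sea-ice edge in austral
summer, and on prevailing winds in flight. `ternwinds` is an R toolkit for
asking how end-of-century climate change bears on each of those systems:

* **Tracking density** — bins GPS/geolocator fixes into 1° *tern-day*
  surfaces (time-to-next-fix attribution, capped gaps, mass-conserving
  Gaussian smoothing) and turns them into per-region weights for the four
  key stopover regions (North Atlantic subpolar gyre, Benguela upwelling,
  Subantarctic Indian Ocean, Southern Ocean).
* **NPP emergence** — multi-model ensemble means, end-of-century change
  maps with ≥ 75 % model-agreement masks, tern-weighted regional net
  primary production series, and two time-of-emergence signal-to-noise
  statistics against a ±1 "normal" envelope:
  sensitive `S:N(y) = (smooth₁₀(NPP)(y) − mean₁₈₅₀₋₁₉₅₀) / σ₁₈₅₀₋₁₉₅₀`,
  and conservative `S:N(y) = 14·b̂_[y, y+14] / σ_[y, y+14]` over a 15-year
  tern lifespan (equal to `14/√((15²−1)/12) ≈ 3.24` on a pure ramp).
* **Sea-ice edge** — the 15 %-concentration edge per 1° longitude
  (first crossing from the north, sub-cell interpolation), monthly and
  decadal climatologies, NPP within a band of the edge in the
  60° W–120° E sector, and fix-to-edge distances.
* **Wind climatology** — multi-model seasonal means per migration phase
  (breeding, southbound, overwinter, northbound), future-minus-historical
  deltas, zonal-mean profiles.
* **vTern simulator** — virtual terns released at 70° S that fly at
  10 m s⁻¹ toward Iceland during the first 14 h of each day, drift with
  the daily 10-m wind while flying, rest motionless the other 10 h, and
  leave the simulation at 60° N; durations, Africa-crossing fractions and
  occupancy maps summarise cohorts.
* **Synthetic climate** — seedable generators for jet-structured winds,
  multi-model NPP ensembles with prescribed trends, seasonally cycling
  retreating sea ice (with an analytic edge oracle), and flyway-shaped
  tracking fixes, so the whole pipeline runs and is tested without any
  climate-model downloads.

Gridded data travel as in-memory `grid_field` objects and long-format CSV
(`read_grid_csv`/`write_grid_csv`); tracking data as CSV with columns
`bird_id, timestamp, lat, lon, device`.

## Worked example

Weight North Atlantic NPP by where tracked terns actually forage, ask when
a strong-forcing decline emerges from interannual variability, and fly a
zero-wind vTern cohort:

```r
library(ternwinds)

tracks <- make_tracks(n_birds = 21, seed = 1)        # synthetic flyway fixes
dens   <- smooth_density(bin_tern_days(tracks), sigma = 1)
w      <- region_weights(dens, tern_regions()$north_atlantic)

cfg <- npp_config(seed = 1, lat_range = c(40, 65), lon_range = c(-60, 0),
                  regions = npp_region_defaults("ssp585")["north_atlantic"])
ens <- make_npp_ensemble(cfg)                         # 12 members, 1850-2100
pc  <- percent_change(multi_model_mean(ens))
sn  <- regional_sn(ens, w, mode = "sensitive")
emergence_year(sn)

cfgv <- vtern_config(n_per_release = 100, release_days = 80L)
migration_stats(simulate_cohort(list(u = 0, v = 0), cfgv, 2000))
```

which prints (formatted):

```
North Atlantic NPP change by 2081-2100: -49.5%
Sensitive S:N emergence: 2019 (sign -1), S:N in 2100 = -15.1
Zero-wind vTern cohort: 100 arrived, duration 28.8 +/- 0.3 days
```

Read: the synthetic ensemble was built with a −50 % end-of-century decline
and the estimator recovers −49.5 %; the tern-weighted signal leaves the
±1-SD envelope of preindustrial variability early in the 21st century and
reaches 15 standard deviations below normal by 2100; and with no wind a
vTern needs about 29 days from the Weddell Sea to 60° N, matching the
great-circle distance at 504 km per flight-day.

## Limitations

The synthetic generator provides statistical structure, not physics:
zonally uniform jets, regionally coherent AR(1) noise, logistic ice
profiles, and a coarse hand-digitised land mask. Reproducing observed
migration statistics (durations of ~30 days with ~4-day spread, ~50 %
Africa crossings) requires real daily 10-m winds from reanalysis or CMIP6
archives, which this package deliberately does not download; its reader
and simulator accept any such fields regridded to 1°.
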