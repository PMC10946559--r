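# Synthetic-climate generators: gridded winds (Gaussian-in-latitude jets),
# multi-model NPP ensembles, seasonally cycling Southern Ocean sea ice, and
# flyway-shaped tracking fixes. Every generator is a pure function of
# (config, seed), so all downstream stages are testable without model
# downloads. Defaults emulate the structure of the CMIP6-era analyses this
# package implements: Historical-era baselines, secular trends ramping in
# the 21st century, AR(1) interannual noise.

#' @keywords internal
.check_finite <- function(x, what) {
  if (!all(is.finite(unlist(x)))) stop("non-finite parameter in ", what)
}

# stationary AR(1) array along the first dimension, marginal SD = sd
#' @keywords internal
.ar1_noise <- function(dim, sd, rho) {
  if (sd == 0) return(array(0, dim))
  eps <- array(stats::rnorm(prod(dim)), dim)
  n <- length(dim)
  out <- eps
  if (rho != 0) {
    innov_sd <- sqrt(1 - rho^2)
    if (n == 1L) {
      for (t in 2:dim[1]) out[t] <- rho * out[t - 1] + innov_sd * eps[t]
    } else {
      m <- matrix(eps, nrow = dim[1])
      for (t in 2:dim[1]) m[t, ] <- rho * m[t - 1, ] + innov_sd * m[t, ]
      out <- array(m, dim)
    }
  }
  out * sd
}

#' @keywords internal
.centres <- function(range) seq(range[1] + 0.5, range[2] - 0.5, by = 1)

# ---------------------------------------------------------------------------
# Wind

#' Specify a zonal jet for the synthetic wind generator
#'
#' @param name jet label.
#' @param center_lat core latitude, degrees north.
#' @param peak peak zonal speed at the core, m s^-1 (negative = easterly).
#' @param width Gaussian half-width in degrees latitude.
#' @param center_trend drift of the core latitude, degrees per century.
#' @param peak_trend change of the peak speed, m s^-1 per century.
#' @return A list of class `jet_spec`.
#' @export
jet_spec <- function(name, center_lat, peak, width,
                     center_trend = 0, peak_trend = 0) {
  .check_finite(list(center_lat, peak, width, center_trend, peak_trend),
                "jet_spec")
  if (width <= 0) stop("jet width must be > 0")
  structure(list(name = name, center_lat = center_lat, peak = peak,
                 width = width, center_trend = center_trend,
                 peak_trend = peak_trend), class = "jet_spec")
}

#' Default jet set: Southern Ocean westerlies, Antarctic coastal easterlies,
#' northern westerlies and the trade-wind belts, with end-of-century
#' strengthening/poleward contraction of the southern westerlies and
#' intensifying coastal easterlies.
#' @export
default_jets <- function() {
  list(
    jet_spec("so_westerlies", -52, 8, 6, center_trend = -3, peak_trend = 2.5),
    jet_spec("antarctic_easterlies", -67, -4, 3, peak_trend = -2.5),
    jet_spec("se_trades", -15, -6, 8),
    jet_spec("ne_trades", 15, -6, 8),
    jet_spec("nh_westerlies", 50, 7, 8, peak_trend = 0.5)
  )
}

#' Configuration for the synthetic wind generator
#'
#' @param seed integer RNG seed (identical seed gives identical fields).
#' @param years inclusive year range `c(first, last)`.
#' @param freq `"daily"`, `"monthly"` or `"annual"` sampling.
#' @param lat_range,lon_range grid edges in degrees; cells are 1 degree with
#'   centres at the half-degrees.
#' @param jets list of [jet_spec()]s (overlaps allowed).
#' @param v_cells list of meridional circulation cells, each
#'   `list(center_lat, center_lon, amplitude, width, amp_trend)` (Gaussian
#'   bumps in the meridional component, e.g. coastal upwelling winds).
#' @param noise_sd marginal SD of the AR(1) wind noise, m s^-1.
#' @param ar1 lag-1 autocorrelation of the noise (0 = white).
#' @param max_speed physical clamp on |wind|, m s^-1.
#' @return A list of class `wind_config`.
#' @export
wind_config <- function(seed = 1L, years = c(1960, 2014), freq = "monthly",
                        lat_range = c(-80, 80), lon_range = c(-70, 30),
                        jets = default_jets(),
                        v_cells = list(list(center_lat = -25, center_lon = 12,
                                            amplitude = 2, width = 8,
                                            amp_trend = 0)),
                        noise_sd = 1, ar1 = 0.3, max_speed = 60) {
  freq <- match.arg(freq, c("daily", "monthly", "annual"))
  .check_finite(list(years, lat_range, lon_range, noise_sd, ar1, max_speed),
                "wind_config")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  stopifnot(years[2] >= years[1])
  structure(list(seed = as.integer(seed), years = years, freq = freq,
                 lat_range = lat_range, lon_range = lon_range, jets = jets,
                 v_cells = v_cells, noise_sd = noise_sd, ar1 = ar1,
                 max_speed = max_speed),
            class = "wind_config")
}

#' Generate paired zonal/meridional wind fields
#'
#' The zonal component is a sum of Gaussian-in-latitude jets whose peak
#' speeds and core latitudes trend linearly over the configured span; the
#' meridional component is a sum of Gaussian cells. AR(1) noise (marginal SD
#' `noise_sd`, lag-1 correlation `ar1`) is added per grid cell.
#'
#' @param config a [wind_config()].
#' @return `list(uas =, vas =)` of [grid_field()]s in m s^-1.
#' @export
make_wind_field <- function(config) {
  stopifnot(inherits(config, "wind_config"))
  time <- switch(config$freq,
                 daily = daily_steps(config$years),
                 monthly = monthly_steps(config$years),
                 annual = annual_steps(config$years))
  lat <- .centres(config$lat_range)
  lon <- .centres(config$lon_range)
  yr_frac <- time$year +
    ifelse(!is.na(time$doy), (time$doy - 0.5) / 365,
           ifelse(!is.na(time$month), (time$month - 0.5) / 12, 0.5))
  cent <- (yr_frac - config$years[1]) / 100  # centuries since span start
  nt <- nrow(time); nlat <- length(lat); nlon <- length(lon)

  u_mean <- matrix(0, nt, nlat)
  for (j in config$jets) {
    peak <- j$peak + j$peak_trend * cent
    ctr <- j$center_lat + j$center_trend * cent
    u_mean <- u_mean + outer(peak, rep(1, nlat)) *
      exp(-0.5 * ((matrix(lat, nt, nlat, byrow = TRUE) - ctr) / j$width)^2)
  }
  v_mean <- array(0, c(nt, nlat, nlon))
  for (cl in config$v_cells) {
    amp <- cl$amplitude + (if (is.null(cl$amp_trend)) 0 else cl$amp_trend) * cent
    sp <- outer(exp(-0.5 * ((lat - cl$center_lat) / cl$width)^2),
                exp(-0.5 * ((lon - cl$center_lon) / cl$width)^2))
    v_mean <- v_mean + array(outer(amp, as.vector(sp)), c(nt, nlat, nlon))
  }

  set.seed(config$seed)
  u <- array(rep(u_mean, nlon), c(nt, nlat, nlon)) +
    .ar1_noise(c(nt, nlat, nlon), config$noise_sd, config$ar1)
  v <- v_mean + .ar1_noise(c(nt, nlat, nlon), config$noise_sd, config$ar1)
  u <- pmin(pmax(u, -config$max_speed), config$max_speed)
  v <- pmin(pmax(v, -config$max_speed), config$max_speed)
  list(uas = grid_field("uas", u, "m s-1", time, lat, lon),
       vas = grid_field("vas", v, "m s-1", time, lat, lon))
}

# ---------------------------------------------------------------------------
# NPP ensemble

#' Default regional NPP structure for the synthetic ensemble
#'
#' Baselines (g C m^-2 day^-1) and fractional end-of-century changes for the
#' four flyway stopover regions. Under the strong-forcing scenario the North
#' Atlantic declines by half, the Benguela weakly declines, the Subantarctic
#' Indian Ocean is near-neutral, and the Southern Ocean increases; the
#' moderate scenario halves the changes.
#'
#' @param scenario `"ssp585"`, `"ssp245"` or `"historical"` (no trend).
#' @export
npp_region_defaults <- function(scenario = "ssp585") {
  scenario <- match.arg(scenario, c("ssp585", "ssp245", "historical"))
  f <- switch(scenario, ssp585 = 1, ssp245 = 0.5, historical = 0)
  boxes <- tern_regions()
  list(
    north_atlantic = list(box = boxes$north_atlantic, baseline = 0.6,
                          change = -0.5 * f),
    benguela = list(box = boxes$benguela, baseline = 0.8, change = -0.1 * f),
    subantarctic_indian = list(box = boxes$subantarctic_indian,
                               baseline = 0.4, change = -0.02 * f),
    southern_ocean = list(box = boxes$southern_ocean, baseline = 0.3,
                          change = 0.2 * f)
  )
}

#' Configuration for the synthetic NPP ensemble
#'
#' Each member is a shared forced signal (regional baseline plus a trend
#' that is flat through 2014, ramps linearly to its full amplitude at the
#' start of the end-of-century window, then holds) plus a model offset and
#' AR(1) interannual noise. The ramp construction makes the prescribed
#' fractional `change` exactly the 2081-2100 mean relative to the 1850-1950
#' mean, which downstream percent-change estimators must recover.
#'
#' @param seed integer RNG seed.
#' @param years annual span, default 1850-2100.
#' @param lat_range,lon_range grid edges (1-degree cells).
#' @param regions list as from [npp_region_defaults()].
#' @param background `list(baseline, change)` outside the regions.
#' @param n_models ensemble size (>= 1).
#' @param inter_model_sd SD of the per-model additive offsets.
#' @param interannual_sd marginal SD of each member's AR(1) interannual
#'   noise (shared across the grid, i.e. regionally coherent variability).
#' @param cell_sd optional extra white noise per cell (spatially incoherent).
#' @param ar1 lag-1 autocorrelation of the interannual noise.
#' @param ramp `c(start, end)` years of the linear trend ramp.
#' @param scenario scenario label carried on the output.
#' @return A list of class `npp_config`.
#' @export
npp_config <- function(seed = 1L, years = c(1850, 2100),
                       lat_range = c(-78, 70), lon_range = c(-180, 180),
                       regions = npp_region_defaults("ssp585"),
                       background = list(baseline = 0.4, change = 0),
                       n_models = 12L, inter_model_sd = 0.05,
                       interannual_sd = 0.02, cell_sd = 0, ar1 = 0.3,
                       ramp = c(2015, 2081), scenario = "SSP5-8.5") {
  if (n_models < 1) stop("n_models must be >= 1")
  if (inter_model_sd < 0 || interannual_sd < 0 || cell_sd < 0)
    stop("SDs must be >= 0")
  for (r in regions)
    if (r$baseline < 0) stop("negative baseline rejected")
  if (background$baseline < 0) stop("negative baseline rejected")
  .check_finite(list(years, lat_range, lon_range, inter_model_sd,
                     interannual_sd, cell_sd, ar1, ramp), "npp_config")
  structure(list(seed = as.integer(seed), years = years,
                 lat_range = lat_range, lon_range = lon_range,
                 regions = regions, background = background,
                 n_models = as.integer(n_models),
                 inter_model_sd = inter_model_sd,
                 interannual_sd = interannual_sd, cell_sd = cell_sd,
                 ar1 = ar1, ramp = ramp, scenario = scenario),
            class = "npp_config")
}

#' @keywords internal
.npp_ramp <- function(year, ramp) {
  pmin(pmax((year - (ramp[1] - 1)) / (ramp[2] - (ramp[1] - 1)), 0), 1)
}

#' Generate a synthetic multi-model NPP ensemble
#'
#' @param config an [npp_config()].
#' @return An [ensemble_set()] of annual `intpp` fields
#'   (g C m^-2 day^-1), clamped at zero, with the per-region true changes
#'   and model offsets attached as attributes for recovery tests.
#' @export
make_npp_ensemble <- function(config) {
  stopifnot(inherits(config, "npp_config"))
  time <- annual_steps(config$years)
  lat <- .centres(config$lat_range)
  lon <- .centres(config$lon_range)
  nt <- nrow(time); nlat <- length(lat); nlon <- length(lon)

  base_map <- matrix(config$background$baseline, nlat, nlon)
  chg_map <- matrix(config$background$change, nlat, nlon)
  for (r in config$regions) {
    inb <- in_region(r$box, lat, lon)
    base_map[inb] <- r$baseline
    chg_map[inb] <- r$change
  }
  ramp <- .npp_ramp(time$year, config$ramp)
  # forced signal: baseline * (1 + change * ramp)
  signal <- array(NA_real_, c(nt, nlat, nlon))
  for (t in seq_len(nt))
    signal[t, , ] <- base_map * (1 + chg_map * ramp[t])

  set.seed(config$seed)
  offsets <- stats::rnorm(config$n_models, 0, config$inter_model_sd)
  members <- vector("list", config$n_models)
  names(members) <- sprintf("model%02d", seq_len(config$n_models))
  for (m in seq_len(config$n_models)) {
    noise <- .ar1_noise(nt, config$interannual_sd, config$ar1)
    v <- signal + offsets[m] + array(rep(noise, nlat * nlon), c(nt, nlat, nlon))
    if (config$cell_sd > 0)
      v <- v + array(stats::rnorm(nt * nlat * nlon, 0, config$cell_sd),
                     c(nt, nlat, nlon))
    v[v < 0] <- 0
    members[[m]] <- grid_field("intpp", v, "g C m-2 day-1", time, lat, lon)
  }
  ens <- ensemble_set(members, variable = "intpp", scenario = config$scenario)
  attr(ens, "true_change") <- vapply(config$regions, `[[`, numeric(1), "change")
  attr(ens, "offsets") <- offsets
  attr(ens, "config") <- config
  ens
}

# ---------------------------------------------------------------------------
# Sea ice

#' Configuration for the synthetic Southern Ocean sea-ice generator
#'
#' Concentration is a logistic function of latitude around a seasonally
#' cycling 50 %-concentration edge latitude which drifts poleward at the
#' configured trend; the 15 % extent contour sits
#' `steepness * log(100/15 - 1)` degrees equatorward of it (see
#' [analytic_ice_edge()]).
#'
#' @param seed integer RNG seed.
#' @param years inclusive year range.
#' @param lat_range,lon_range grid edges (1-degree cells).
#' @param edge_mean annual-mean 50 % edge latitude, degrees north.
#' @param amplitude seasonal amplitude of the edge latitude, degrees.
#' @param peak_month month of maximum (most equatorward) extent.
#' @param retreat edge trend, degrees per century (negative = poleward).
#' @param steepness logistic width of the marginal ice zone, degrees.
#' @param noise_sd AR(1) noise on the monthly edge latitude, degrees.
#' @param ar1 lag-1 autocorrelation of the edge noise.
#' @return A list of class `ice_config`.
#' @export
ice_config <- function(seed = 1L, years = c(1979, 2018),
                       lat_range = c(-78, -40), lon_range = c(-180, 180),
                       edge_mean = -62, amplitude = 6, peak_month = 9L,
                       retreat = -5, steepness = 1.5, noise_sd = 0.3,
                       ar1 = 0.3) {
  .check_finite(list(years, lat_range, lon_range, edge_mean, amplitude,
                     retreat, steepness, noise_sd, ar1), "ice_config")
  if (steepness <= 0) stop("steepness must be > 0")
  if (amplitude < 0 || noise_sd < 0) stop("amplitude and noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), years = years,
                 lat_range = lat_range, lon_range = lon_range,
                 edge_mean = edge_mean, amplitude = amplitude,
                 peak_month = as.integer(peak_month), retreat = retreat,
                 steepness = steepness, noise_sd = noise_sd, ar1 = ar1),
            class = "ice_config")
}

#' @keywords internal
.ice_edge50 <- function(config, year, month) {
  yr_frac <- year + (month - 0.5) / 12
  config$edge_mean +
    config$amplitude * cos(2 * pi * (month - config$peak_month) / 12) +
    config$retreat * (yr_frac - config$years[1]) / 100
}

#' Deterministic edge latitude of the synthetic ice field
#'
#' The exact latitude at which the noise-free synthetic concentration equals
#' `threshold` percent; the construction oracle for edge-extraction tests.
#'
#' @param config an [ice_config()].
#' @param year,month time of interest.
#' @param threshold concentration threshold, percent.
#' @export
analytic_ice_edge <- function(config, year, month, threshold = 15) {
  .ice_edge50(config, year, month) +
    config$steepness * log(100 / threshold - 1)
}

#' Generate a monthly synthetic sea-ice concentration series
#'
#' @param config an [ice_config()].
#' @return A monthly `siconc` [grid_field()] in percent.
#' @export
make_seaice_series <- function(config) {
  stopifnot(inherits(config, "ice_config"))
  time <- monthly_steps(config$years)
  lat <- .centres(config$lat_range)
  lon <- .centres(config$lon_range)
  nt <- nrow(time)
  edge <- .ice_edge50(config, time$year, time$month)
  set.seed(config$seed)
  edge <- edge + .ar1_noise(nt, config$noise_sd, config$ar1)
  conc <- array(NA_real_, c(nt, length(lat), length(lon)))
  for (t in seq_len(nt)) {
    prof <- 100 * stats::plogis((edge[t] - lat) / config$steepness)
    conc[t, , ] <- matrix(prof, length(lat), length(lon))
  }
  grid_field("siconc", conc, "%", time, lat, lon)
}

# ---------------------------------------------------------------------------
# Tracks

#' Default Atlantic-flyway waypoint table
#'
#' A coarse southbound route from Iceland through the North Atlantic
#' subpolar gyre, along West Africa to the Benguela upwelling, across the
#' Subantarctic Indian Ocean, and into the Weddell Sea sector of the
#' Southern Ocean, with dwell times at the stopover regions.
#'
#' @return data.frame with columns `lat`, `lon`, `dwell_days`.
#' @export
flyway_waypoints <- function() {
  data.frame(
    lat = c(64.5, 55, 45, 25, 5, -12, -25, -33, -40, -43, -55, -63, -66, -69),
    lon = c(-22, -35, -28, -20, -15, -2, 8, 14, 40, 70, 60, 10, -20, -45),
    dwell_days = c(0, 8, 4, 0, 0, 0, 10, 4, 0, 10, 0, 8, 12, 20)
  )
}

#' Generate synthetic tern tracking fixes
#'
#' Birds move along the waypoint route at a constant travel speed, pausing
#' `dwell_days` at each waypoint; fixes are sampled at the device interval
#' with Gaussian positional noise. The first `n_gps` birds carry GPS devices
#' (18-h fixes, metre-scale accuracy); the rest carry geolocators (daily
#' fixes, degree-scale noise, with optional equinox gap windows when light
#' curves cannot resolve latitude).
#'
#' @param n_birds number of birds (>= 1).
#' @param waypoints data.frame of `lat`, `lon`, `dwell_days` (>= 2 rows).
#' @param fix_interval geolocator fix interval in hours.
#' @param noise_sd geolocator positional noise SD in degrees
#'   (about 1.7 degrees ~ 185 km).
#' @param seed integer RNG seed; a fixed seed gives a byte-identical CSV.
#' @param n_gps number of GPS birds (interval 18 h, noise 0.02 degrees).
#' @param start_date first possible departure, `"YYYY-MM-DD"` (UTC).
#' @param speed_kmday travel speed between waypoints, km per day.
#' @param equinox_gaps drop geolocator fixes within 10 days of the
#'   equinoxes?
#' @return A `track_set`: data.frame with `bird_id`, `timestamp` (POSIXct
#'   UTC), `lat`, `lon`, `device`; nominal device intervals (h) attached as
#'   attribute `nominal_interval_h`.
#' @export
make_tracks <- function(n_birds = 21L, waypoints = flyway_waypoints(),
                        fix_interval = 24, noise_sd = 1.0, seed = 1L,
                        n_gps = 2L, start_date = "2017-08-01",
                        speed_kmday = 700, equinox_gaps = TRUE) {
  if (n_birds < 1) stop("zero birds rejected: n_birds must be >= 1")
  if (nrow(waypoints) < 2) stop("need at least 2 waypoints")
  stopifnot(fix_interval > 0, noise_sd >= 0, speed_kmday > 0)
  set.seed(as.integer(seed))
  n_gps <- min(n_gps, n_birds)

  # leg lengths (great-circle) -> cumulative travel+dwell time along route
  p <- cbind(waypoints$lon, waypoints$lat)
  leg_km <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                     p[-1, , drop = FALSE], r = 6371000) / 1000
  leg_days <- leg_km / speed_kmday
  # event times: arrive wp_i, leave wp_i (after dwell)
  t_arrive <- c(0, cumsum(leg_days + waypoints$dwell_days[-nrow(waypoints)]))
  t_leave <- t_arrive + waypoints$dwell_days
  total_days <- t_arrive[length(t_arrive)] + waypoints$dwell_days[nrow(waypoints)]

  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  pos_at <- function(td) {
    # piecewise position at route-time td (days)
    i <- findInterval(td, t_arrive)
    i <- pmin(pmax(i, 1L), nrow(waypoints))
    lat <- waypoints$lat[i]; lon <- waypoints$lon[i]
    moving <- td > t_leave[i] & i < nrow(waypoints)
    if (any(moving)) {
      j <- i[moving]
      f <- (td[moving] - t_leave[j]) / leg_days[j]
      f <- pmin(pmax(f, 0), 1)
      lat[moving] <- waypoints$lat[j] + f * (waypoints$lat[j + 1] - waypoints$lat[j])
      lon[moving] <- waypoints$lon[j] + f * (waypoints$lon[j + 1] - waypoints$lon[j])
    }
    cbind(lat, lon)
  }

  out <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    gps <- b <= n_gps
    interval_h <- if (gps) 18 else fix_interval
    sd_b <- if (gps) 0.02 else noise_sd
    depart <- stats::runif(1, 0, 10)            # staggered departures (days)
    fix_td <- seq(0, total_days, by = interval_h / 24)
    pos <- pos_at(fix_td)
    ts <- t0 + (depart + fix_td) * 86400
    keep <- rep(TRUE, length(fix_td))
    if (!gps && equinox_gaps) {
      doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
      keep <- !(abs(doy - 265) <= 10 | abs(doy - 79) <= 10)
    }
    lat <- pos[, 1] + stats::rnorm(length(fix_td), 0, sd_b)
    lon <- pos[, 2] + stats::rnorm(length(fix_td), 0, sd_b)
    out[[b]] <- data.frame(
      bird_id = sprintf("bird%02d", b),
      timestamp = ts[keep],
      lat = pmin(pmax(lat[keep], -89.9), 89.9),
      lon = .wrap_lon(lon[keep]),
      device = if (gps) "GPS" else "GLS"
    )
  }
  tracks <- do.call(rbind, out)
  as_track_set(tracks)
}

#' Coerce a data.frame of fixes to a track_set
#'
#' @param x data.frame with columns `bird_id`, `timestamp`, `lat`, `lon`,
#'   `device` (`"GPS"` or `"GLS"`).
#' @param nominal_interval_h named nominal fix intervals per device, hours.
#' @export
as_track_set <- function(x, nominal_interval_h = c(GPS = 18, GLS = 24)) {
  stopifnot(all(c("bird_id", "timestamp", "lat", "lon", "device") %in% names(x)))
  if (any(!is.finite(x$lat)) || any(x$lat < -90) || any(x$lat > 90))
    stop("fixes outside [-90, 90] latitude rejected")
  if (any(!is.finite(x$lon))) stop("non-finite longitudes rejected")
  x <- x[order(x$bird_id, x$timestamp), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, nominal_interval_h = nominal_interval_h,
            class = c("track_set", "data.frame"))
}
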