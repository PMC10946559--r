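# Virtual arctic tern ("vTern") northbound migration simulator. vTerns are
# particles that, during the active part of each day, fly at constant
# airspeed along the great-circle bearing towards the target colony region
# while being advected by the near-surface wind; during inactive hours they
# neither fly nor drift. Forward-Euler integration on the sphere at an
# hourly time step; deterministic given the wind forcing.

#' vTern simulation configuration
#'
#' Defaults encode the reference experiment: release at 70 S across the
#' Weddell Sea sector (60-40 W, endpoints included), on days 80/90/100 of
#' the year, 2000 vTerns per release day (6000 per year); constant airspeed
#' 10 m s^-1 towards Iceland (65 N, 20 W) during the first 14 h of each UTC
#' day; removal on crossing 60 N; 1-h Euler steps with positions recorded
#' every 2 h.
#'
#' @param release_lat release latitude, degrees.
#' @param release_lon_range release longitude span `c(west, east)`.
#' @param n_per_release vTerns per release day (>= 2; equally spaced,
#'   endpoints inclusive).
#' @param release_days days of year of the releases (no-leap calendar).
#' @param airspeed constant airspeed, m s^-1.
#' @param active_hours flying hours per day, counted from 00:00 UTC of the
#'   release day; `active_hours + inactive` must equal 24.
#' @param target `c(lat, lon)` the vTerns steer towards.
#' @param exit_lat latitude whose crossing ends a migration (arrival).
#' @param step_hours Euler step, hours.
#' @param record_every position-recording interval, hours.
#' @param max_days cap after which a vTern is flagged as failed.
#' @param earth_radius_km spherical Earth radius.
#' @param heading `"great_circle"` (bearing recomputed every step) or
#'   `"rhumb"` (constant-bearing loxodrome steering, for sensitivity tests).
#' @return A list of class `vtern_config`.
#' @export
vtern_config <- function(release_lat = -70, release_lon_range = c(-60, -40),
                         n_per_release = 2000L,
                         release_days = c(80L, 90L, 100L),
                         airspeed = 10, active_hours = 14,
                         target = c(lat = 65, lon = -20), exit_lat = 60,
                         step_hours = 1, record_every = 2, max_days = 120,
                         earth_radius_km = 6371,
                         heading = c("great_circle", "rhumb")) {
  heading <- match.arg(heading)
  if (n_per_release < 2) stop("n_per_release must be >= 2")
  if (airspeed < 0) stop("airspeed must be >= 0")
  if (active_hours <= 0 || active_hours > 24)
    stop("active_hours must be in (0, 24]")
  if (exit_lat >= target[["lat"]]) stop("exit_lat must be south of the target")
  structure(list(release_lat = release_lat,
                 release_lon_range = release_lon_range,
                 n_per_release = as.integer(n_per_release),
                 release_days = as.integer(release_days),
                 airspeed = airspeed, active_hours = active_hours,
                 target = target, exit_lat = exit_lat,
                 step_hours = step_hours, record_every = record_every,
                 max_days = max_days, earth_radius_km = earth_radius_km,
                 heading = heading),
            class = "vtern_config")
}

#' Release positions and times for one year's cohort
#'
#' @param config a [vtern_config()].
#' @param year release year.
#' @return data.frame `id`, `lat`, `lon`, `release_day`, `year`;
#'   `n_per_release` longitudes equally spaced inclusive of both endpoints,
#'   repeated for each release day. Deterministic.
#' @export
release_positions <- function(config, year = 2000L) {
  stopifnot(inherits(config, "vtern_config"))
  lons <- seq(config$release_lon_range[1], config$release_lon_range[2],
              length.out = config$n_per_release)
  n <- config$n_per_release * length(config$release_days)
  data.frame(id = seq_len(n),
             lat = config$release_lat,
             lon = rep(lons, length(config$release_days)),
             release_day = rep(config$release_days,
                               each = config$n_per_release),
             year = as.integer(year))
}

#' Initial great-circle bearing between points (degrees clockwise from N)
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  b <- atan2(sin(dl) * cos(p2),
             cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (b * 180 / pi) %% 360
}

#' @keywords internal
.rhumb_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- .wrap_lon(lon2 - lon1) * pi / 180
  dpsi <- log(tan(pi / 4 + p2 / 2) / tan(pi / 4 + p1 / 2))
  (atan2(dl, dpsi) * 180 / pi) %% 360
}

#' Advance vTern positions by one time step
#'
#' During an active step the ground velocity is the wind vector plus the
#' airspeed along the current bearing to the target; a forward-Euler step
#' on the sphere updates latitude by `v dt / R` and longitude by
#' `u dt / (R cos(lat))`, with longitudes wrapped to \[-180, 180). During
#' inactive steps vTerns neither fly nor drift. Positions reaching
#' |lat| >= 89.5 are flagged aborted (the lon-lat metric degenerates).
#'
#' @param lat,lon current positions, degrees (vectorised).
#' @param u,v wind components at the positions, m s^-1.
#' @param config a [vtern_config()].
#' @param active logical: is this an active (flying) step?
#' @param dt_hours step length, hours.
#' @return `list(lat =, lon =, aborted =)`.
#' @export
step_vtern <- function(lat, lon, u, v, config, active = TRUE,
                       dt_hours = config$step_hours) {
  if (!active)
    return(list(lat = lat, lon = lon, aborted = rep(FALSE, length(lat))))
  brg <- if (config$heading == "great_circle")
    gc_bearing(lat, lon, config$target[["lat"]], config$target[["lon"]])
  else
    .rhumb_bearing(lat, lon, config$target[["lat"]], config$target[["lon"]])
  br <- brg * pi / 180
  ut <- u + config$airspeed * sin(br)
  vt <- v + config$airspeed * cos(br)
  dt <- dt_hours * 3600
  R <- config$earth_radius_km * 1000
  new_lat <- lat + vt * dt / R * 180 / pi
  new_lon <- .wrap_lon(lon + ut * dt / (R * cos(lat * pi / 180)) * 180 / pi)
  aborted <- abs(new_lat) >= 89.5
  list(lat = new_lat, lon = new_lon, aborted = aborted)
}

# bilinear wind sampling on cell centres; wraps in longitude when the grid
# spans the full circle, clamps otherwise (and always clamps in latitude)
#' @keywords internal
.bilinear <- function(mat, lat_axis, lon_axis, lat, lon) {
  nlat <- length(lat_axis); nlon <- length(lon_axis)
  dlat <- lat_axis[2] - lat_axis[1]; dlon <- lon_axis[2] - lon_axis[1]
  fi <- (lat - lat_axis[1]) / dlat + 1
  fi <- pmin(pmax(fi, 1), nlat)
  i0 <- pmin(floor(fi), nlat - 1L); wi <- fi - i0
  global <- (nlon * dlon) >= 360 - 1e-9
  fj <- (lon - lon_axis[1]) / dlon + 1
  if (global) {
    fj <- ((fj - 1) %% nlon) + 1
    j0 <- floor(fj); wj <- fj - j0
    j1 <- ifelse(j0 >= nlon, 1L, j0 + 1L)
  } else {
    fj <- pmin(pmax(fj, 1), nlon)
    j0 <- pmin(floor(fj), nlon - 1L); wj <- fj - j0
    j1 <- j0 + 1L
  }
  idx <- function(i, j) mat[cbind(i, j)]
  (1 - wi) * ((1 - wj) * idx(i0, j0) + wj * idx(i0, j1)) +
    wi * ((1 - wj) * idx(i0 + 1L, j0) + wj * idx(i0 + 1L, j1))
}

#' Simulate a year's vTern cohort
#'
#' Integrates every vTern from its release (00:00 UTC on the release day)
#' until it crosses the exit latitude (arrival), exceeds `max_days`
#' (failure), or reaches a polar singularity (abort). Wind is sampled
#' bilinearly in space and nearest-day in time from daily `uas`/`vas`
#' fields; a `list(u =, v =)` of constants gives a uniform-wind experiment
#' (the zero-wind oracle, tailwind dominance tests). Deterministic given
#' its inputs.
#'
#' @param winds `list(uas =, vas =)` of daily [grid_field()]s covering the
#'   simulation window, or `list(u =, v =)` scalars for uniform wind.
#' @param config a [vtern_config()].
#' @param year simulation year (used to index the wind time axis).
#' @return A `trajectory_set`: list with `birds` (per-vTern summary:
#'   release, status, `duration_days`), `positions` (2-hourly records:
#'   `id`, `hour`, `lat`, `lon`), `n_released`, `config`, `year`.
#' @export
simulate_cohort <- function(winds, config = vtern_config(), year = 2000L) {
  stopifnot(inherits(config, "vtern_config"))
  uniform <- !is.null(winds[["u"]])
  if (!uniform && (is.null(winds$uas) || is.null(winds$vas)))
    stop("winds must be list(uas=, vas=) grid fields or list(u=, v=) scalars")
  rel <- release_positions(config, year)
  n <- nrow(rel)
  lat <- rel$lat + numeric(n); lon <- rel$lon
  status <- rep(0L, n)                  # 0 pending 1 active 2 arrived 3 failed 4 aborted
  release_hour <- (rel$release_day - 1L) * 24L
  duration <- rep(NA_real_, n)

  h0 <- min(release_hour)
  h_end <- max(release_hour) + config$max_days * 24L
  rec <- vector("list", 0L)

  day_cache <- list(doy = NA_integer_)
  get_day_winds <- function(doy_abs) {
    yr <- year + (doy_abs - 1L) %/% 365L
    doy <- (doy_abs - 1L) %% 365L + 1L
    ti <- which(winds$uas$time$year == yr & winds$uas$time$doy == doy)
    if (length(ti) != 1L)
      stop("wind fields missing day ", doy, " of year ", yr)
    list(u = winds$uas$values[ti, , ], v = winds$vas$values[ti, , ])
  }

  for (h in seq.int(h0, h_end - 1L)) {
    status[status == 0L & release_hour == h] <- 1L
    expired <- status == 1L & (h - release_hour) >= config$max_days * 24L
    status[expired] <- 3L
    live <- which(status == 1L)
    if (h %% config$record_every == 0 && length(live))
      rec[[length(rec) + 1L]] <- data.frame(id = rel$id[live], hour = h,
                                            lat = lat[live], lon = lon[live])
    if (!length(live)) {
      if (all(status != 0L) && !any(status == 1L) &&
          h > max(release_hour)) break
      next
    }
    active <- (h %% 24L) < config$active_hours
    if (!active) next
    if (uniform) {
      u <- rep(winds[["u"]], length(live)); v <- rep(winds[["v"]], length(live))
    } else {
      doy_abs <- h %/% 24L + 1L
      if (!identical(day_cache$doy, doy_abs))
        day_cache <- c(get_day_winds(doy_abs), list(doy = doy_abs))
      u <- .bilinear(day_cache$u, winds$uas$lat, winds$uas$lon,
                     lat[live], lon[live])
      v <- .bilinear(day_cache$v, winds$vas$lat, winds$vas$lon,
                     lat[live], lon[live])
    }
    st <- step_vtern(lat[live], lon[live], u, v, config, active = TRUE)
    lat[live] <- st$lat; lon[live] <- st$lon
    ab <- live[st$aborted]
    status[ab] <- 4L
    arr <- live[!st$aborted & st$lat >= config$exit_lat]
    if (length(arr)) {
      status[arr] <- 2L
      duration[arr] <- (h + 1L - release_hour[arr]) / 24
    }
  }
  status[status == 1L] <- 3L            # still aloft at the cap

  birds <- data.frame(id = rel$id, release_day = rel$release_day,
                      release_lat = rel$lat, release_lon = rel$lon,
                      status = c("pending", "active", "arrived", "failed",
                                 "aborted")[status + 1L],
                      duration_days = duration)
  positions <- if (length(rec)) do.call(rbind, rec)
               else data.frame(id = integer(), hour = integer(),
                               lat = numeric(), lon = numeric())
  structure(list(birds = birds, positions = positions, n_released = n,
                 config = config, year = year),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  tb <- table(x$birds$status)
  cat(sprintf("<trajectory_set> year %d: %d released (%s)\n", x$year,
              x$n_released,
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Migration duration statistics
#'
#' @param tset a `trajectory_set`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return `list(mean_days, sd_days, n_arrived, n_failed, n_aborted)`;
#'   statistics are over arrived vTerns only and are `NA` with zero
#'   arrivals.
#' @export
migration_stats <- function(tset, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(tset, "trajectory_set"))
  d <- tset$birds$duration_days[tset$birds$status == "arrived"]
  list(mean_days = if (length(d)) mean(d) else NA_real_,
       sd_days = if (length(d) >= 2)
         (if (sd_type == "sample") stats::sd(d) else .pop_sd(d))
         else if (length(d) == 1) 0 else NA_real_,
       n_arrived = length(d),
       n_failed = sum(tset$birds$status == "failed"),
       n_aborted = sum(tset$birds$status == "aborted"))
}

#' Fraction of vTerns crossing a land region
#'
#' A vTern counts as crossing when at least one of its recorded (2-hourly)
#' positions falls in a land cell inside the region box; cells transited
#' entirely between records are not seen (a documented discretisation of
#' the recording interval).
#'
#' @param tset a `trajectory_set`.
#' @param land_mask logical 1-degree land matrix with `lat`/`lon`
#'   attributes (default [land_mask_1deg()]).
#' @param region `c(lon_min, lon_max, lat_min, lat_max)` box; the default
#'   bounds the African continent.
#' @return Fraction of released vTerns with a recorded land position in the
#'   region.
#' @export
land_crossing_fraction <- function(tset, land_mask = NULL,
                                   region = c(-20, 52, -35, 38)) {
  stopifnot(inherits(tset, "trajectory_set"))
  if (is.null(land_mask)) land_mask <- land_mask_1deg()
  if (!any(land_mask)) stop("empty land mask rejected")
  p <- tset$positions
  if (!nrow(p)) return(0)
  sel <- p$lon >= region[1] & p$lon <= region[2] &
         p$lat >= region[3] & p$lat <= region[4]
  p <- p[sel, , drop = FALSE]
  if (!nrow(p)) return(0)
  mlat <- attr(land_mask, "lat"); mlon <- attr(land_mask, "lon")
  i <- match(.cell_floor(p$lat) + 0.5, mlat)
  j <- match(.cell_floor(.wrap_lon(p$lon)) + 0.5, mlon)
  ok <- !is.na(i) & !is.na(j)
  on_land <- ok
  on_land[ok] <- land_mask[cbind(i[ok], j[ok])]
  length(unique(p$id[on_land])) / tset$n_released
}

#' Occupancy map of a vTern cohort
#'
#' Per 1-degree cell, the fraction of released vTerns whose recorded track
#' ever entered the cell (distinct vTerns, not position counts). Cells
#' below `mask_below` are kept but flagged in the `mask` attribute, the
#' rendering convention for occupancy maps.
#'
#' @param tset a `trajectory_set`.
#' @param lat_range,lon_range grid edges of the output map.
#' @param mask_below flagging threshold (fraction, default 1 %).
#' @return An `occupancy_grid` matrix (fractions in \[0, 1\]) with
#'   `lat`/`lon`, `mask` (TRUE where 0 < occupancy < `mask_below`) and
#'   `n_released` attributes.
#' @export
occupancy_map <- function(tset, lat_range = c(-90, 90),
                          lon_range = c(-180, 180), mask_below = 0.01) {
  stopifnot(inherits(tset, "trajectory_set"))
  lat <- .centres(lat_range); lon <- .centres(lon_range)
  occ <- matrix(0, length(lat), length(lon))
  p <- tset$positions
  if (nrow(p)) {
    i <- match(.cell_floor(p$lat) + 0.5, lat)
    j <- match(.cell_floor(.wrap_lon(p$lon)) + 0.5, lon)
    ok <- !is.na(i) & !is.na(j)
    cells <- unique(data.frame(id = p$id[ok], i = i[ok], j = j[ok]))
    counts <- stats::aggregate(id ~ i + j, data = cells, FUN = length)
    occ[cbind(counts$i, counts$j)] <- counts$id / tset$n_released
  }
  structure(occ, lat = lat, lon = lon, mask_below = mask_below,
            mask = occ > 0 & occ < mask_below,
            n_released = tset$n_released, class = "occupancy_grid")
}
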