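# Shared fixture builders: tiny fields and ensembles constructed in code.

# constant-valued field over a small grid
const_field <- function(value, variable = "intpp", units = "g C m-2 day-1",
                        years = c(1850, 2100), lat = seq(40.5, 44.5),
                        lon = seq(-9.5, -5.5), freq = "annual") {
  time <- switch(freq, annual = annual_steps(years),
                 monthly = monthly_steps(years), daily = daily_steps(years))
  grid_field(variable, array(value, c(nrow(time), length(lat), length(lon))),
             units, time, lat, lon)
}

# ensemble whose members add per-model offsets to a shared field
offset_ensemble <- function(base_field, offsets, scenario = "SSP5-8.5") {
  members <- lapply(offsets, function(o) {
    grid_field(base_field$variable, base_field$values + o, base_field$units,
               base_field$time, base_field$lat, base_field$lon)
  })
  names(members) <- sprintf("m%02d", seq_along(members))
  ensemble_set(members, scenario = scenario)
}

# uniform region weights over a grid
uniform_weights <- function(lat, lon, region = "test") {
  structure(matrix(1 / (length(lat) * length(lon)), length(lat), length(lon)),
            lat = lat, lon = lon, region = region,
            class = "region_weights")
}

# hand-built track_set: one bird, fixes at given hours/positions
fixes_track <- function(lat, lon, hours, bird = "b1", device = "GLS",
                        t0 = as.POSIXct("2008-01-05 00:00:00", tz = "UTC")) {
  as_track_set(data.frame(bird_id = bird, timestamp = t0 + hours * 3600,
                          lat = lat, lon = lon, device = device))
}

# activity-clock-exact zero-wind oracle: full 504-km days plus the
# remaining kilometres at the 36 km/h active flight speed, from the
# great-circle distance to the exit-latitude crossing
gc_oracle_days <- function(lon0, cfg = vtern_config()) {
  path <- geosphere::gcIntermediate(c(lon0, cfg$release_lat),
                                    c(cfg$target[["lon"]], cfg$target[["lat"]]),
                                    n = 20000, addStartEnd = TRUE)
  i <- which(path[, 2] >= cfg$exit_lat)[1]
  d_km <- geosphere::distHaversine(c(lon0, cfg$release_lat), path[i, ],
                                   r = cfg$earth_radius_km * 1000) / 1000
  km_day <- cfg$airspeed * 3.6 * cfg$active_hours
  full <- floor(d_km / km_day)
  rem_h <- (d_km - full * km_day) / (cfg$airspeed * 3.6)
  list(naive = d_km / km_day, exact = full + rem_h / 24)
}

# minimal trajectory_set for statistics tests
manual_tset <- function(durations, status = "arrived", positions = NULL,
                        n_released = length(durations)) {
  birds <- data.frame(id = seq_along(durations), release_day = 80,
                      release_lat = -70, release_lon = -50,
                      status = status, duration_days = durations)
  if (is.null(positions))
    positions <- data.frame(id = integer(), hour = integer(),
                            lat = numeric(), lon = numeric())
  structure(list(birds = birds, positions = positions,
                 n_released = n_released, config = vtern_config(),
                 year = 2000L),
            class = "trajectory_set")
}
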