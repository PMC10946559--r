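# Virtual-tern simulator: kinematics, oracles, conservation, summaries.

test_that("release positions are equally spaced with both endpoints", {
  cfg3 <- vtern_config(n_per_release = 3, release_days = 80L)
  expect_equal(release_positions(cfg3)$lon, c(-60, -50, -40))
  lons <- seq(-60, -40, length.out = 2000)
  expect_equal(diff(lons)[1], 20 / 1999)
  expect_equal(nrow(release_positions(vtern_config())), 6000)
  expect_error(vtern_config(n_per_release = 1), ">= 2")
})

test_that("the great-circle bearing matches an independent implementation", {
  set.seed(15)
  for (k in 1:20) {
    p1 <- c(runif(1, -180, 179), runif(1, -80, 80))
    p2 <- c(runif(1, -180, 179), runif(1, -80, 80))
    expect_equal(gc_bearing(p1[2], p1[1], p2[2], p2[1]),
                 geosphere::bearing(p1, p2, f = 0) %% 360, tolerance = 1e-6)
  }
})

test_that("one active hour at 10 m/s with no wind moves 36 km along the bearing", {
  cfg <- vtern_config()
  # due north: start on the target meridian, south of the target
  st <- step_vtern(10, -20, 0, 0, cfg, active = TRUE)
  expect_equal(st$lat - 10, 36000 / 6371000 * 180 / pi, tolerance = 1e-12)
  expect_equal(st$lon, -20)

  # inactive hour: position unchanged whatever the wind
  st2 <- step_vtern(10, -20, 25, -15, cfg, active = FALSE)
  expect_equal(st2$lat, 10)
  expect_equal(st2$lon, -20)

  # a pure 10 m/s headwind opposing the bearing cancels the displacement
  b <- gc_bearing(-30, -45, cfg$target[["lat"]], cfg$target[["lon"]]) * pi / 180
  st3 <- step_vtern(-30, -45, -10 * sin(b), -10 * cos(b), cfg, active = TRUE)
  expect_equal(st3$lat, -30, tolerance = 1e-9)
  expect_equal(st3$lon, -45, tolerance = 1e-9)
})

test_that("with airspeed zero, drift equals the wind vector exactly", {
  cfg <- vtern_config(n_per_release = 2, release_days = 80L, airspeed = 0,
                      max_days = 2, record_every = 1)
  ts <- simulate_cohort(list(u = 3, v = 4), cfg, 2000)
  p1 <- ts$positions[ts$positions$id == 1, ]
  p1 <- p1[order(p1$hour), ]
  R <- 6371000
  for (k in seq_len(nrow(p1) - 1)) {
    hod <- p1$hour[k] %% 24
    dlat <- p1$lat[k + 1] - p1$lat[k]
    dlon <- p1$lon[k + 1] - p1$lon[k]
    if (hod < 14) {
      expect_equal(dlat, 4 * 3600 / R * 180 / pi, tolerance = 1e-12)
      expect_equal(dlon, 3 * 3600 / (R * cos(p1$lat[k] * pi / 180)) * 180 / pi,
                   tolerance = 1e-9)
    } else {
      expect_identical(dlat, 0)
      expect_identical(dlon, 0)
    }
  }
})

test_that("zero-wind durations match the great-circle oracle", {
  cfg <- vtern_config(n_per_release = 5, release_days = 80L)
  ts <- simulate_cohort(list(u = 0, v = 0), cfg, 2000)
  expect_true(all(ts$birds$status == "arrived"))
  for (k in seq_len(nrow(ts$birds))) {
    o <- gc_oracle_days(ts$birds$release_lon[k], cfg)
    expect_lt(abs(ts$birds$duration_days[k] - o$exact) / o$exact, 0.01)
  }
})

test_that("simulation is bit-identical across runs and responds to tailwind", {
  cfg <- vtern_config(n_per_release = 4, release_days = 80L)
  a <- simulate_cohort(list(u = 0, v = 0), cfg, 2000)
  b <- simulate_cohort(list(u = 0, v = 0), cfg, 2000)
  expect_identical(a$positions, b$positions)
  expect_identical(a$birds, b$birds)

  tail5 <- simulate_cohort(list(u = 0, v = 5), cfg, 2000)
  expect_true(all(tail5$birds$duration_days < a$birds$duration_days))
  # small-curvature limit: duration approaches distance / ((airspeed+w)*14h)
  o <- gc_oracle_days(-50, cfg)
  d_km <- o$naive * 504
  lower <- d_km / ((10 + 5) * 3.6 * 14) / 1.05
  expect_gt(min(tail5$birds$duration_days), lower)
})

test_that("per-record displacement respects the speed bound", {
  cfg <- vtern_config(n_per_release = 3, release_days = 80L)
  ts <- simulate_cohort(list(u = 4, v = 3), cfg, 2000)
  wmax <- 5
  for (id in 1:3) {
    p <- ts$positions[ts$positions$id == id, ]
    p <- p[order(p$hour), ]
    d <- geosphere::distHaversine(cbind(p$lon[-nrow(p)], p$lat[-nrow(p)]),
                                  cbind(p$lon[-1], p$lat[-1]),
                                  r = 6371000) / 1000
    dh <- diff(p$hour)
    bound <- (10 + wmax) * 3.6 * dh * 1.001
    expect_true(all(d <= bound))
  }
})

test_that("released = arrived + failed + aborted", {
  # a cap too short to finish: every vTern fails
  cfg_fail <- vtern_config(n_per_release = 3, release_days = 80L, max_days = 5)
  tf <- simulate_cohort(list(u = 0, v = 0), cfg_fail, 2000)
  s <- migration_stats(tf)
  expect_equal(s$n_arrived + s$n_failed + s$n_aborted, tf$n_released)
  expect_equal(s$n_failed, 3)
  expect_true(is.na(s$mean_days))

  # polar releases towards a near-pole target trigger the abort guard
  cfg_ab <- vtern_config(release_lat = 85, release_lon_range = c(-10, 10),
                         n_per_release = 3, release_days = 80L,
                         target = c(lat = 89.9, lon = 0), exit_lat = 89.8,
                         max_days = 10)
  ta <- simulate_cohort(list(u = 0, v = 0), cfg_ab, 2000)
  sa <- migration_stats(ta)
  expect_gt(sa$n_aborted, 0)
  expect_equal(sa$n_arrived + sa$n_failed + sa$n_aborted, ta$n_released)
})

test_that("duration statistics follow the documented conventions", {
  ts <- manual_tset(c(20, 40))
  s <- migration_stats(ts)
  expect_equal(s$mean_days, 30)
  expect_equal(s$sd_days, sqrt(200))        # sample SD default
  expect_equal(migration_stats(ts, sd_type = "population")$sd_days, 10)
  sd0 <- migration_stats(manual_tset(rep(25, 4)))
  expect_equal(sd0$mean_days, 25)
  expect_equal(sd0$sd_days, 0)
})

test_that("Africa-crossing detection uses recorded land positions", {
  ocean <- manual_tset(30, positions = data.frame(
    id = 1, hour = c(0, 2), lat = c(-30, -29), lon = c(-25, -25)))
  expect_equal(land_crossing_fraction(ocean), 0)

  over_land <- manual_tset(30, positions = data.frame(
    id = 1, hour = c(0, 2), lat = c(-30, 0.3), lon = c(-25, 20.4)))
  expect_equal(land_crossing_fraction(over_land), 1)  # (0 N, 20 E) is land

  # forced eastward drift pushes the cohort over Africa
  cfg <- vtern_config(n_per_release = 10, release_days = 80L)
  drift <- simulate_cohort(list(u = 8, v = 0), cfg, 2000)
  calm <- simulate_cohort(list(u = 0, v = 0), cfg, 2000)
  expect_gt(land_crossing_fraction(drift), land_crossing_fraction(calm))
  expect_error(land_crossing_fraction(calm, land_mask = structure(
    matrix(FALSE, 2, 2), lat = c(0.5, 1.5), lon = c(0.5, 1.5))), "empty")
})

test_that("occupancy counts distinct vTerns per cell", {
  cfg <- vtern_config(n_per_release = 5, release_days = 80L)
  ts <- simulate_cohort(list(u = 2, v = 0), cfg, 2000)
  occ <- occupancy_map(ts)
  lat <- attr(occ, "lat"); lon <- attr(occ, "lon")
  # brute-force set-union oracle
  brute <- matrix(0, length(lat), length(lon))
  for (id in unique(ts$positions$id)) {
    p <- ts$positions[ts$positions$id == id, ]
    cells <- unique(cbind(match(floor(p$lat) + 0.5, lat),
                          match(floor(p$lon) + 0.5, lon)))
    brute[cells] <- brute[cells] + 1
  }
  expect_equal(unclass(occ), brute / ts$n_released, ignore_attr = TRUE)
  expect_true(all(occ >= 0 & occ <= 1))
  # each release cell holds at least its own vTern
  expect_true(all(occ[cbind(match(-69.5, lat),
                            match(floor(seq(-60, -40, length.out = 5)) + 0.5,
                                  lon))] >= 1 / ts$n_released))

  # a single vTern yields a binary map
  one <- occupancy_map(manual_tset(30, positions = data.frame(
    id = 1, hour = c(0, 2, 4), lat = c(-70, -69, -68), lon = -50),
    n_released = 1))
  expect_true(all(one %in% c(0, 1)))
})

test_that("wind gaps in the forcing raise an informative error", {
  w <- make_wind_field(wind_config(years = c(2000, 2000), freq = "daily",
                                   lat_range = c(-75, -60),
                                   lon_range = c(-65, -35), noise_sd = 0))
  # truncate the forcing so the window is not covered
  short <- w
  keep <- which(w$uas$time$doy <= 85)
  for (v in c("uas", "vas")) {
    short[[v]]$values <- w[[v]]$values[keep, , , drop = FALSE]
    short[[v]]$time <- w[[v]]$time[keep, ]
  }
  cfg <- vtern_config(n_per_release = 2, release_days = 80L, max_days = 10)
  expect_error(simulate_cohort(short, cfg, 2000), "missing day")
})
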