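# Ensemble post-processing and signal-to-noise emergence statistics.

test_that("multi-model mean averages cellwise with missing-value handling", {
  f1 <- const_field(1); f3 <- const_field(3)
  ens <- ensemble_set(list(a = f1, b = f3))
  expect_true(all(multi_model_mean(ens)$values == 2))
  expect_equal(multi_model_mean(ensemble_set(list(only = f3)))$values,
               f3$values)

  # brute-force re-summation oracle with a missing cell
  set.seed(10)
  members <- lapply(1:12, function(i) {
    f <- const_field(0)
    f$values[] <- rnorm(length(f$values))
    f
  })
  members[[1]]$values[1, 1, 1] <- NA       # pairwise-complete at this cell
  names(members) <- sprintf("m%02d", 1:12)
  ens12 <- ensemble_set(members)
  mmm <- multi_model_mean(ens12)
  arr <- simplify2array(lapply(members, `[[`, "values"))
  brute <- apply(arr, 1:3, mean, na.rm = TRUE)
  dimnames(brute) <- NULL
  expect_equal(mmm$values, brute, tolerance = 1e-12)
})

test_that("grid mismatch between members is rejected", {
  f1 <- const_field(1)
  f2 <- const_field(1, lat = seq(41.5, 45.5))
  expect_error(ensemble_set(list(a = f1, b = f2)), "mismatch")
})

test_that("percent change does the arithmetic and masks a zero baseline", {
  f <- const_field(0.2)
  nt <- nrow(f$time)
  f$values[f$time$year >= 2081, , ] <- 0.1
  pc <- percent_change(f)
  expect_true(all(abs(pc$values - (-50)) < 1e-9))

  g <- const_field(0.1)
  g$values[g$time$year >= 2081, , ] <- 0.2
  expect_true(all(abs(percent_change(g)$values - 100) < 1e-9))

  h <- const_field(1)
  h$values[, 1, 1] <- 0                     # zero-baseline cell masked
  expect_true(is.na(percent_change(h)$values[1, 1]))
})

test_that("model agreement implements the 9-of-12 rule", {
  base <- const_field(1)
  mk <- function(delta) {
    f <- const_field(1)
    f$values[f$time$year >= 2081, , ] <- 1 + delta
    f
  }
  ens <- ensemble_set(stats::setNames(
    lapply(c(rep(-0.2, 9), rep(0.2, 3)), mk), sprintf("m%02d", 1:12)))
  ag <- model_agreement(ens)
  expect_equal(ag$fraction$values[1, 1], 0.75)
  expect_true(ag$mask$values[1, 1])

  ens6 <- ensemble_set(stats::setNames(
    lapply(c(rep(-0.2, 3), rep(0.2, 3)), mk), sprintf("m%02d", 1:6)))
  ag6 <- model_agreement(ens6)
  expect_equal(ag6$fraction$values[1, 1], 0.5)
  expect_false(ag6$mask$values[1, 1])

  ens_all <- ensemble_set(stats::setNames(lapply(rep(0.2, 5), mk),
                                          sprintf("m%02d", 1:5)))
  expect_equal(model_agreement(ens_all)$fraction$values[1, 1], 1)
})

test_that("weighted regional series is the dot product with the weights", {
  set.seed(11)
  f <- const_field(0)
  f$values[] <- rnorm(length(f$values))
  lat <- f$lat; lon <- f$lon

  w1 <- uniform_weights(lat, lon)
  w1[, ] <- 0; w1[2, 3] <- 1               # all weight on one cell
  expect_equal(weighted_regional_series(f, w1)$value, f$values[, 2, 3])

  wu <- uniform_weights(lat, lon)          # uniform weights = regional mean
  expect_equal(weighted_regional_series(f, wu)$value,
               apply(f$values, 1, mean), tolerance = 1e-12)

  wr <- uniform_weights(lat, lon)          # random weights: dot-product oracle
  wr[, ] <- runif(length(wr)); wr[, ] <- wr / sum(wr)
  expect_equal(weighted_regional_series(f, wr)$value,
               as.vector(matrix(f$values, nrow(f$time)) %*% as.vector(unclass(wr))),
               tolerance = 1e-12)
})

test_that("multi_model_mean and weighted_regional_series commute", {
  set.seed(12)
  members <- stats::setNames(lapply(1:5, function(i) {
    f <- const_field(0); f$values[] <- rnorm(length(f$values)); f
  }), sprintf("m%02d", 1:5))
  ens <- ensemble_set(members)
  w <- uniform_weights(members[[1]]$lat, members[[1]]$lon)
  w[, ] <- runif(length(w)); w[, ] <- w / sum(w)
  via_mmm <- weighted_regional_series(multi_model_mean(ens), w)$value
  via_members <- rowMeans(sapply(members, function(m)
    weighted_regional_series(m, w)$value))
  expect_equal(via_mmm, via_members, tolerance = 1e-12)
})

test_that("sensitive S:N is zero for a series at its baseline mean and 2 for a 2-SD step", {
  years <- 1850:2100
  flat <- rep(5, length(years))
  expect_error(sn_sensitive(flat, years), "noise")   # zero noise degenerate

  base_pattern <- rep_len(c(1, -1), length(years))   # alternating +/-1
  x <- 5 + base_pattern
  x[years > 1950] <- 5                               # noise only in baseline
  sn0 <- sn_sensitive(flat, years, noise = 1)        # series == baseline mean
  expect_true(all(abs(sn0$sn) < 1e-12))

  # step of +2 SD after 2050 on an alternating baseline (1950 set to 0 so
  # the 101-year baseline mean is exactly zero)
  y <- 5 + base_pattern
  y[years == 1950] <- 5
  bl <- y[years <= 1950] - 5
  sd_b <- sqrt(mean(bl^2))                           # population SD, mean 0
  y[years >= 2051] <- 5 + 2 * sd_b + base_pattern[years >= 2051]
  sn <- sn_sensitive(y, years)
  mid <- sn$year %in% 2060:2090                      # windows clear of the step
  expect_true(all(abs(sn$sn[mid] - 2) < 1e-8))
  em <- emergence_year(sn)
  expect_true(em$year >= 2046 && em$year <= 2055)    # within the smoothing window
  expect_equal(em$sign, 1)
})

test_that("conservative S:N has the arithmetic-sequence closed form", {
  years <- 2000:2060
  expect_true(all(sn_conservative(rep(3, 61), years)$sn == 0))
  for (b in c(0.01, 1, -2.5)) {
    ramp <- 100 + b * seq_along(years)
    sn <- sn_conservative(ramp, years, lifespan = 15)
    expect_equal(sn$sn, rep(sign(b) * 14 / sqrt((15^2 - 1) / 12), nrow(sn)),
                 tolerance = 1e-9)
  }
  expect_error(sn_conservative(rep(1, 10), 2000:2009), "shorter")
})

test_that("both S:N statistics are invariant to positive rescaling", {
  set.seed(13)
  years <- 1850:2100
  x <- 2 + cumsum(rnorm(length(years), 0.002, 0.05))
  x <- x - min(x) + 1
  for (cc in c(0.1, 3.7)) {
    expect_equal(sn_sensitive(cc * x, years)$sn, sn_sensitive(x, years)$sn,
                 tolerance = 1e-9)
    expect_equal(sn_conservative(cc * x, years)$sn,
                 sn_conservative(x, years)$sn, tolerance = 1e-9)
  }
})

test_that("conservative S:N null matches the closed-form correlation null", {
  # sn = 3.2404 r with r the window correlation against time, so under white
  # noise P(|sn| > 1) = P(|t_13| > r0 sqrt(13)/sqrt(1-r0^2)), r0 = 1/3.2404
  set.seed(14)
  n_rep <- 2000
  hits <- vapply(seq_len(n_rep), function(i)
    abs(sn_conservative(rnorm(15), 2000:2014)$sn) > 1, logical(1))
  r0 <- sqrt((15^2 - 1) / 12) / 14
  p_closed <- 2 * stats::pt(-r0 * sqrt(13) / sqrt(1 - r0^2), df = 13)
  mc_se <- sqrt(p_closed * (1 - p_closed) / n_rep)
  expect_lt(abs(mean(hits) - p_closed), 4 * mc_se)
})

test_that("emergence year finds the first envelope crossing", {
  sn <- structure(data.frame(year = 2000:2100, sn = rep(0, 101)),
                  class = c("sn_series", "data.frame"))
  expect_true(is.na(emergence_year(sn)$year))
  sn$sn <- seq(-0.5, 2.5, length.out = 101)
  expect_equal(emergence_year(sn)$year, sn$year[which(sn$sn > 1)[1]])
  # constructed crossing at 2062
  sn$sn <- ifelse(sn$year >= 2062, -1.2, 0.2)
  expect_equal(emergence_year(sn)$year, 2062)
  expect_equal(emergence_year(sn)$sign, -1)
})

test_that("emergence year is non-increasing in trend magnitude", {
  years <- vapply(c(-0.5, -0.3, -0.15), function(chg) {
    regions <- npp_region_defaults("ssp585")["north_atlantic"]
    regions$north_atlantic$change <- chg
    cfg <- npp_config(seed = 21, lat_range = c(40, 65), lon_range = c(-60, -40),
                      regions = regions)
    ens <- make_npp_ensemble(cfg)
    w <- uniform_weights(ens$members[[1]]$lat, ens$members[[1]]$lon,
                         region = "north_atlantic")
    emergence_year(regional_sn(ens, w, mode = "sensitive"))$year
  }, numeric(1))
  expect_true(all(diff(years) >= 0))
})
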