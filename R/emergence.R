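# Multi-model ensemble post-processing and time-of-emergence statistics:
# multi-model means, end-of-century change maps with model-agreement
# hatching, tern-weighted regional NPP series, and the sensitive /
# conservative signal-to-noise statistics with their +/-1 "normal" envelope.

#' Construct an ensemble of aligned gridded fields
#'
#' @param members named list of [grid_field()]s sharing variable, grid and
#'   time axis.
#' @param variable variable name (checked against members).
#' @param scenario scenario label (`"Historical"`, `"SSP2-4.5"`,
#'   `"SSP5-8.5"`, ...).
#' @return An object of class `ensemble_set`.
#' @export
ensemble_set <- function(members, variable = members[[1]]$variable,
                         scenario = "Historical") {
  stopifnot(length(members) >= 1)
  if (is.null(names(members)) || anyDuplicated(names(members)))
    stop("members must be uniquely named")
  ref <- members[[1]]
  for (m in members) {
    if (!identical(m$variable, variable))
      stop("all members must carry variable '", variable, "'")
    if (!isTRUE(all.equal(m$lat, ref$lat)) ||
        !isTRUE(all.equal(m$lon, ref$lon)) ||
        !identical(dim(m$values), dim(ref$values)) ||
        !identical(m$time$year, ref$time$year))
      stop("grid/time mismatch between ensemble members")
  }
  structure(list(members = members, variable = variable, scenario = scenario),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %s, %d members, scenario %s\n",
              x$variable, length(x$members), x$scenario))
  invisible(x)
}

#' Unweighted multi-model mean
#'
#' Cellwise arithmetic mean across members; missing cells are ignored
#' pairwise and all-missing cells propagate as missing.
#'
#' @param ensemble an [ensemble_set()].
#' @return A [grid_field()] on the common grid.
#' @export
multi_model_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_set"))
  ref <- ensemble$members[[1]]
  s <- array(0, dim(ref$values))
  n <- array(0L, dim(ref$values))
  for (m in ensemble$members) {
    ok <- is.finite(m$values)
    s[ok] <- s[ok] + m$values[ok]
    n <- n + ok
  }
  out <- s / n
  out[n == 0L] <- NA_real_
  grid_field(ref$variable, out, ref$units, ref$time, ref$lat, ref$lon)
}

#' Percent change between two period means
#'
#' `100 * (future - baseline) / baseline`, with cells whose baseline
#' magnitude is below `eps` times the global-mean baseline magnitude masked
#' out (relative change is undefined there).
#'
#' @param field a [grid_field()] (e.g. the multi-model mean).
#' @param baseline,future year ranges, default preindustrial 1850-1950 and
#'   end-of-century 2081-2100.
#' @param months optional months-of-year subset for both period means.
#' @param eps relative mask threshold on the baseline.
#' @return A [grid_slice()] in percent.
#' @export
percent_change <- function(field, baseline = c(1850, 1950),
                           future = c(2081, 2100), months = NULL,
                           eps = 1e-6) {
  b <- period_mean(field, baseline, months)$values
  f <- period_mean(field, future, months)$values
  thr <- eps * mean(abs(b), na.rm = TRUE)
  pc <- 100 * (f - b) / b
  pc[!is.finite(pc) | abs(b) < thr] <- NA_real_
  grid_slice(pc, field$lat, field$lon, paste0(field$variable, "_pct_change"),
             "%", period = future)
}

#' Model agreement on the direction of change
#'
#' Per cell, the fraction of members whose sign of (future minus baseline)
#' matches the majority sign; zero changes count with neither sign. The mask
#' flags cells where at least `min_agree` of the members agree (the
#' 9-of-12 = 75 % rule by default).
#'
#' @param ensemble an [ensemble_set()] (>= 2 members).
#' @param baseline,future year ranges.
#' @param months optional months-of-year subset.
#' @param min_agree agreement fraction required for the mask.
#' @return `list(fraction =, mask =)` of [grid_slice()]s.
#' @export
model_agreement <- function(ensemble, baseline = c(1850, 1950),
                            future = c(2081, 2100), months = NULL,
                            min_agree = 0.75) {
  stopifnot(inherits(ensemble, "ensemble_set"), length(ensemble$members) >= 2)
  ref <- ensemble$members[[1]]
  npos <- matrix(0L, length(ref$lat), length(ref$lon))
  nneg <- npos
  for (m in ensemble$members) {
    d <- period_mean(m, future, months)$values -
      period_mean(m, baseline, months)$values
    npos <- npos + (is.finite(d) & d > 0)
    nneg <- nneg + (is.finite(d) & d < 0)
  }
  nmem <- length(ensemble$members)
  frac <- pmax(npos, nneg) / nmem
  list(fraction = grid_slice(frac, ref$lat, ref$lon, "agreement", "fraction"),
       mask = grid_slice(frac >= min_agree, ref$lat, ref$lon,
                         "agreement_mask", "boolean"))
}

#' Tern-weighted regional series
#'
#' Collapses a field to one value per time step as the weighted sum over
#' cells, with weights renormalised over the non-missing cells of each step.
#'
#' @param field a [grid_field()].
#' @param weights a `region_weights` matrix from [region_weights()] (or any
#'   non-negative matrix on the field grid summing to 1).
#' @param years,months optional time selection.
#' @return A `regional_series`: data.frame `year`, `month`, `value` with the
#'   region name attached.
#' @export
weighted_regional_series <- function(field, weights, years = NULL,
                                     months = NULL) {
  wlat <- attr(weights, "lat"); wlon <- attr(weights, "lon")
  wmat <- unclass(weights)
  if (!is.null(wlat) &&
      (!isTRUE(all.equal(wlat, field$lat)) || !isTRUE(all.equal(wlon, field$lon)))) {
    # align a weights grid defined on a superset (e.g. a global density
    # grid) onto the field grid, renormalising to the covered cells
    i <- match(field$lat, wlat); j <- match(field$lon, wlon)
    if (anyNA(i) || anyNA(j))
      stop("weights grid does not cover the field grid")
    wmat <- wmat[i, j, drop = FALSE]
    tot <- sum(wmat)
    if (tot <= 0) stop("no weight mass falls on the field grid")
    if (tot < 1 - 1e-9)
      warning(sprintf("field grid covers %.1f%% of the region weight mass; renormalising",
                      100 * tot))
    wmat <- wmat / tot
  }
  w <- as.vector(wmat)
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  idx <- time_index(field, years, months)
  M <- matrix(field$values, nrow = dim(field$values)[1])[idx, , drop = FALSE]
  ok <- is.finite(M)
  M[!ok] <- 0
  num <- M %*% w
  den <- ok %*% w            # renormalise over non-missing cells
  vals <- as.vector(ifelse(den > 0, num / den, NA_real_))
  structure(data.frame(year = field$time$year[idx],
                       month = field$time$month[idx],
                       value = vals),
            region = attr(weights, "region"), variable = field$variable,
            class = c("regional_series", "data.frame"))
}

# annual mean of a regional_series (pass-through if already annual)
#' @keywords internal
.annualise <- function(series) {
  if (all(is.na(series$month)) || !anyDuplicated(series$year))
    return(series[c("year", "value")])
  stats::aggregate(value ~ year, data = series, FUN = mean)
}

#' @keywords internal
.series_years_values <- function(series, years) {
  if (inherits(series, "data.frame")) {
    s <- .annualise(series)
    list(years = s$year, values = s$value)
  } else {
    if (is.null(years)) {
      if (is.null(names(series)))
        stop("supply `years` or a named/regional series")
      years <- as.integer(names(series))
    }
    list(years = years, values = as.numeric(series))
  }
}

#' Sensitive signal-to-noise (emergence relative to preindustrial normal)
#'
#' Signal: the decadally smoothed series (centred running mean, truncated at
#' the series edges) minus the baseline-period mean. Noise: the SD of the
#' annual values over the baseline period (1850-1950 by default), i.e. the
#' envelope of "normal" interannual variation. A year with |S:N| > 1 falls
#' outside the envelope of conditions the population is adapted to; the sign
#' follows the direction of the trend.
#'
#' @param series annual series: a `regional_series`, a named numeric vector,
#'   or a numeric vector with `years`.
#' @param years year vector when `series` is unnamed numeric.
#' @param baseline "normal conditions" period `c(first, last)`.
#' @param smooth_window running-mean width in years (decadal default).
#' @param noise optional externally estimated noise SD (e.g. the ensemble
#'   mean of per-member interannual SDs); default is the SD of the baseline
#'   annual values of `series` itself.
#' @param detrend_noise estimate the noise on linearly detrended baseline
#'   values instead of raw values.
#' @return An `sn_series`: data.frame `year`, `sn` with mode and noise
#'   metadata attached; the normal envelope is \[-1, 1\].
#' @export
sn_sensitive <- function(series, years = NULL, baseline = c(1850, 1950),
                         smooth_window = 10, noise = NULL,
                         detrend_noise = FALSE) {
  s <- .series_years_values(series, years)
  yr <- s$years; x <- s$values
  bi <- yr >= baseline[1] & yr <= baseline[2]
  if (!any(bi)) stop("series does not cover the baseline period")
  if (is.null(noise)) {
    xb <- x[bi]
    if (detrend_noise) xb <- stats::residuals(stats::lm(xb ~ yr[bi]))
    noise <- .pop_sd(xb)
  }
  if (!is.finite(noise) || noise <= 0)
    stop("zero or undefined noise: degenerate baseline series")
  sm <- .running_mean(x, smooth_window)
  sn <- (sm - mean(x[bi])) / noise
  structure(data.frame(year = yr, sn = sn),
            mode = "sensitive", baseline = baseline, noise = noise,
            smooth_window = smooth_window, envelope = c(-1, 1),
            class = c("sn_series", "data.frame"))
}

#' Conservative signal-to-noise (emergence within a tern generation)
#'
#' For each fledging year y, the signal is the least-squares linear trend of
#' the series over \[y, y + lifespan - 1\] times (lifespan - 1) -- the total
#' change over an average tern lifespan -- and the noise is the (population)
#' SD of the raw values over the same window. |S:N| > 1 means a generation
#' experiences change larger than the variability it could have adapted to.
#' Windows are reported against their start (fledging) year.
#'
#' @inheritParams sn_sensitive
#' @param lifespan window length in years (average adult lifespan, 15).
#' @return An `sn_series` data.frame `year`, `sn` (one row per fledging year
#'   with a full window).
#' @export
sn_conservative <- function(series, years = NULL, lifespan = 15) {
  s <- .series_years_values(series, years)
  yr <- s$years; x <- s$values
  n <- length(x)
  if (n < lifespan) stop("series shorter than the lifespan window")
  starts <- seq_len(n - lifespan + 1)
  tt <- seq_len(lifespan)
  sxx <- sum((tt - mean(tt))^2)
  sn <- vapply(starts, function(i) {
    w <- x[i:(i + lifespan - 1)]
    slope <- sum((tt - mean(tt)) * (w - mean(w))) / sxx
    noise <- .pop_sd(w)
    if (!is.finite(noise) || noise == 0) {
      if (slope == 0) return(0)  # constant series: no change, no noise
      stop("zero-variance window with non-zero trend at year ", yr[i])
    }
    slope * (lifespan - 1) / noise
  }, numeric(1))
  structure(data.frame(year = yr[starts], sn = sn),
            mode = "conservative", lifespan = lifespan, envelope = c(-1, 1),
            class = c("sn_series", "data.frame"))
}

#' @keywords internal
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# centred running mean, truncated at the edges; even widths take
# floor((w-1)/2) years before and ceiling((w-1)/2) after the centre year
#' @keywords internal
.running_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  before <- floor((w - 1) / 2); after <- ceiling((w - 1) / 2)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - before):min(n, i + after)]), numeric(1))
}

#' First year of emergence from the normal envelope
#'
#' @param sn an `sn_series`.
#' @param threshold envelope half-width (1 by default).
#' @return `list(year =, sign =)`; both `NA` if the series never leaves the
#'   envelope.
#' @export
emergence_year <- function(sn, threshold = 1) {
  i <- which(abs(sn$sn) > threshold)
  if (!length(i)) return(list(year = NA_integer_, sign = NA_real_))
  list(year = sn$year[i[1]], sign = sign(sn$sn[i[1]]))
}

#' Regional emergence pipeline
#'
#' Runs the full chain for one region: multi-model mean, tern-weighted
#' regional series, and the requested S:N statistic. Because averaging N
#' models damps internal variability by about 1/sqrt(N), the noise for the
#' sensitive statistic is by default estimated as the ensemble mean of the
#' per-member baseline-period SDs of the weighted series (the variability a
#' bird actually experiences), not the SD of the multi-model-mean series;
#' set `noise_source = "series"` for the latter.
#'
#' @param ensemble an [ensemble_set()] of `intpp` fields.
#' @param weights region weights from [region_weights()].
#' @param mode `"sensitive"` or `"conservative"`.
#' @param baseline,smooth_window,lifespan passed to the S:N statistics.
#' @param noise_source `"members"` (default) or `"series"`.
#' @return An `sn_series`.
#' @export
regional_sn <- function(ensemble, weights,
                        mode = c("sensitive", "conservative"),
                        baseline = c(1850, 1950), smooth_window = 10,
                        lifespan = 15,
                        noise_source = c("members", "series")) {
  mode <- match.arg(mode)
  noise_source <- match.arg(noise_source)
  mmm <- multi_model_mean(ensemble)
  series <- weighted_regional_series(mmm, weights)
  if (mode == "conservative")
    return(sn_conservative(series, lifespan = lifespan))
  noise <- NULL
  if (noise_source == "members") {
    sds <- vapply(ensemble$members, function(m) {
      s <- .annualise(weighted_regional_series(m, weights))
      .pop_sd(s$value[s$year >= baseline[1] & s$year <= baseline[2]])
    }, numeric(1))
    noise <- mean(sds)
  }
  sn_sensitive(series, baseline = baseline, smooth_window = smooth_window,
               noise = noise)
}
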