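# Core gridded-field container: one variable on a regular time x lat x lon
# grid with a 365-day (no-leap) calendar, the common denominator of regridded
# Earth-system-model output.

#' @keywords internal
noleap_mdays <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' @keywords internal
.month_of_doy <- rep.int(1:12, noleap_mdays)

#' Time axes on the 365-day calendar
#'
#' Build time tables (`year`, `month`, `doy`) for annual, monthly or daily
#' fields on the no-leap calendar used by most climate models.
#'
#' @param years two-element integer range `c(first, last)`, inclusive.
#' @param months integer subset of 1:12 (monthly axis only).
#' @return A data.frame with columns `year`, `month`, `doy`; `month`/`doy`
#'   are `NA` where the axis does not resolve them.
#' @export
annual_steps <- function(years) {
  yr <- seq.int(years[1], years[2])
  data.frame(year = yr, month = NA_integer_, doy = NA_integer_)
}

#' @rdname annual_steps
#' @export
monthly_steps <- function(years, months = 1:12) {
  yr <- seq.int(years[1], years[2])
  data.frame(year = rep(yr, each = length(months)),
             month = rep(as.integer(months), length(yr)),
             doy = NA_integer_)
}

#' @rdname annual_steps
#' @export
daily_steps <- function(years) {
  yr <- seq.int(years[1], years[2])
  data.frame(year = rep(yr, each = 365L),
             month = rep(.month_of_doy, length(yr)),
             doy = rep(1:365, length(yr)))
}

#' Construct a gridded field
#'
#' A `grid_field` holds one variable as a 3-D array over (time, lat, lon) on
#' a regular latitude-longitude grid (cell centres), with units and a no-leap
#' time table. Sea-ice concentration (`siconc`) is clamped to \[0, 100\] %.
#'
#' @param variable variable name (e.g. `"uas"`, `"vas"`, `"intpp"`,
#'   `"siconc"`).
#' @param values numeric array, `dim = c(nrow(time), length(lat), length(lon))`.
#' @param units unit string; required (no unit-less fields).
#' @param time time table as returned by [annual_steps()], [monthly_steps()]
#'   or [daily_steps()].
#' @param lat,lon cell-centre coordinates, strictly ascending; `lat` in
#'   \[-90, 90\], `lon` in \[-180, 180).
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(variable, values, units, time, lat, lon) {
  stopifnot(is.character(variable), nzchar(variable),
            is.character(units), nzchar(units))
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(!is.finite(lat)) || any(diff(lat) <= 0) || min(lat) < -90 || max(lat) > 90)
    stop("`lat` must be finite, strictly ascending and within [-90, 90]")
  if (any(!is.finite(lon)) || any(diff(lon) <= 0) || min(lon) < -180 || max(lon) >= 180)
    stop("`lon` must be finite, strictly ascending and within [-180, 180)")
  if (!is.data.frame(time) || !all(c("year", "month", "doy") %in% names(time)))
    stop("`time` must be a data.frame with columns year, month, doy")
  values <- as.array(values)
  if (length(dim(values)) != 3L ||
      !identical(dim(values), c(nrow(time), length(lat), length(lon))))
    stop("`values` must have dim c(n_time, n_lat, n_lon) = c(",
         nrow(time), ", ", length(lat), ", ", length(lon), ")")
  if (variable == "siconc") values <- pmin(pmax(values, 0), 100)
  structure(list(variable = variable, values = values, units = units,
                 time = time, lat = lat, lon = lon),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]  %d time x %d lat x %d lon\n",
              x$variable, x$units, nrow(x$time), length(x$lat), length(x$lon)))
  cat(sprintf("  years %d-%d; lat %.1f..%.1f; lon %.1f..%.1f\n",
              min(x$time$year), max(x$time$year),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Select time-step indices of a field
#'
#' @param field a [grid_field()].
#' @param years `NULL` or range `c(first, last)` (inclusive).
#' @param months `NULL` or integer subset of 1:12.
#' @return Integer indices into the field's time axis.
#' @export
time_index <- function(field, years = NULL, months = NULL) {
  keep <- rep(TRUE, nrow(field$time))
  if (!is.null(years))
    keep <- keep & field$time$year >= years[1] & field$time$year <= years[2]
  if (!is.null(months)) {
    if (all(is.na(field$time$month)))
      stop("field has no month resolution; cannot select months")
    keep <- keep & field$time$month %in% months
  }
  which(keep)
}

#' A single time-collapsed grid (lat x lon matrix with coordinates)
#'
#' @param values numeric matrix `length(lat)` x `length(lon)`.
#' @param lat,lon cell-centre coordinates.
#' @param variable,units metadata carried through from the parent field.
#' @param period,months the averaging period/months, for provenance.
#' @return An object of class `grid_slice`.
#' @export
grid_slice <- function(values, lat, lon, variable = "field", units = "",
                       period = NULL, months = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  structure(list(values = values, lat = lat, lon = lon,
                 variable = variable, units = units,
                 period = period, months = months),
            class = "grid_slice")
}

#' @export
print.grid_slice <- function(x, ...) {
  cat(sprintf("<grid_slice> %s [%s]  %d lat x %d lon\n",
              x$variable, x$units, length(x$lat), length(x$lon)))
  invisible(x)
}

#' Time-mean of a field over a period (and optional months-of-year)
#'
#' Collapses the time axis by averaging all steps in `period` whose month is
#' in `months` (e.g. July-September means for the northern hemisphere).
#' Missing cells are ignored pairwise; an all-missing cell stays missing.
#'
#' @param field a [grid_field()].
#' @param period year range `c(first, last)`.
#' @param months optional integer subset of 1:12.
#' @return A [grid_slice()].
#' @export
period_mean <- function(field, period, months = NULL) {
  idx <- time_index(field, years = period, months = months)
  if (length(idx) == 0L) stop("empty time selection for period_mean")
  sub <- field$values[idx, , , drop = FALSE]
  m <- apply(sub, c(2L, 3L), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  grid_slice(m, field$lat, field$lon, field$variable, field$units,
             period = period, months = months)
}

# cell index helpers: 1-degree cells [i, i+1) with integer edges
#' @keywords internal
.cell_floor <- function(x) floor(x)

#' @keywords internal
.wrap_lon <- function(lon) ((lon + 180) %% 360) - 180
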