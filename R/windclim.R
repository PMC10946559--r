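# Seasonal multi-model wind climatologies per migration phase,
# future-minus-historical deltas, and zonal-mean profiles.

#' Migration-phase averaging window
#'
#' Fixed month defaults per phase: breeding May-August (high-latitude North
#' Atlantic), southbound August-October (mid-Atlantic/Indian), overwinter
#' November-March (Southern Ocean; the cross-year window is labelled by the
#' January year), northbound April-May (Atlantic).
#'
#' @param phase one of `"breeding"`, `"southbound"`, `"overwinter"`,
#'   `"northbound"`.
#' @param months optional override of the month set.
#' @return A list of class `phase_window`.
#' @export
phase_window <- function(phase = c("breeding", "southbound", "overwinter",
                                   "northbound"),
                         months = NULL) {
  phase <- match.arg(phase)
  if (is.null(months))
    months <- switch(phase,
                     breeding = 5:8, southbound = 8:10,
                     overwinter = c(11, 12, 1, 2, 3), northbound = 4:5)
  structure(list(phase = phase, months = as.integer(months)),
            class = "phase_window")
}

#' Phase-mean multi-model wind
#'
#' Multi-model mean of each wind component over a phase's months and a year
#' range (historical 1960-2014 or end-of-century 2080-2099).
#'
#' @param uas_ens,vas_ens [ensemble_set()]s of the zonal and meridional
#'   components.
#' @param window a [phase_window()].
#' @param years averaging period `c(first, last)`.
#' @return `list(uas =, vas =)` of [grid_slice()]s.
#' @export
phase_mean_wind <- function(uas_ens, vas_ens, window, years) {
  stopifnot(inherits(window, "phase_window"))
  u <- period_mean(multi_model_mean(uas_ens), years, window$months)
  v <- period_mean(multi_model_mean(vas_ens), years, window$months)
  list(uas = u, vas = v)
}

#' Future-minus-historical wind change
#'
#' @param future,historical phase-mean pairs from [phase_mean_wind()] (or
#'   single [grid_slice()]s).
#' @return Componentwise difference, same structure as the inputs.
#' @export
wind_delta <- function(future, historical) {
  one <- function(f, h) {
    if (!isTRUE(all.equal(f$lat, h$lat)) || !isTRUE(all.equal(f$lon, h$lon)))
      stop("grid mismatch between future and historical fields")
    grid_slice(f$values - h$values, f$lat, f$lon,
               paste0(f$variable, "_delta"), f$units)
  }
  if (inherits(future, "grid_slice")) return(one(future, historical))
  list(uas = one(future$uas, historical$uas),
       vas = one(future$vas, historical$vas))
}

#' Zonal-mean wind profile
#'
#' Mean over longitudes at each latitude within a band (a pure along-
#' latitude average: no cosine-latitude weighting, since each profile value
#' describes conditions along its own constant latitude).
#'
#' @param field a [grid_slice()] or single-step [grid_field()].
#' @param lat_band,lon_band coordinate ranges `c(min, max)`; `NULL` = all.
#' @return data.frame `lat`, `mean` (m s^-1).
#' @export
zonal_mean_profile <- function(field, lat_band = NULL, lon_band = NULL) {
  if (inherits(field, "grid_field")) {
    if (nrow(field$time) != 1L)
      stop("collapse the time axis (period_mean) before profiling")
    field <- grid_slice(field$values[1, , ], field$lat, field$lon,
                        field$variable, field$units)
  }
  lat <- field$lat; lon <- field$lon
  li <- if (is.null(lat_band)) rep(TRUE, length(lat))
        else lat >= lat_band[1] & lat <= lat_band[2]
  lj <- if (is.null(lon_band)) rep(TRUE, length(lon))
        else lon >= lon_band[1] & lon <= lon_band[2]
  if (!any(li) || !any(lj)) stop("empty latitude/longitude band")
  m <- field$values[li, lj, drop = FALSE]
  data.frame(lat = lat[li], mean = rowMeans(m, na.rm = TRUE))
}
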