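# Southern Ocean sea-ice edge extraction and summaries: the per-longitude
# latitude of the 15 %-concentration contour, monthly/decadal mean edges,
# NPP along the edge sector, and distance of tracking fixes to the edge.

#' @keywords internal
.edge_from_matrix <- function(conc, lat, lon, threshold) {
  # scan each longitude column from north to south; first threshold
  # crossing, linearly interpolated between the bracketing cells
  nlat <- length(lat)
  ord <- order(lat, decreasing = TRUE)   # north -> south
  edge <- rep(NA_real_, length(lon))
  for (j in seq_along(lon)) {
    col <- conc[ord, j]
    la <- lat[ord]
    ok <- is.finite(col)
    if (!any(ok)) next
    col <- col[ok]; la <- la[ok]
    hit <- which(col >= threshold)
    if (!length(hit)) next
    i <- hit[1]
    if (i == 1L) {
      edge[j] <- la[1]                   # ice reaches the grid's north edge
    } else {
      c_n <- col[i - 1]; c_s <- col[i]
      edge[j] <- la[i - 1] +
        (threshold - c_n) * (la[i] - la[i - 1]) / (c_s - c_n)
    }
  }
  edge
}

#' Extract the sea-ice edge for one month
#'
#' Per 1-degree longitude column, the northernmost latitude at which the
#' concentration reaches the threshold (ties at exactly the threshold
#' belong to ice), linearly interpolated between the bracketing cells; a
#' column that never reaches the threshold is missing. This per-longitude
#' "first crossing from the north" is robust to interior polynyas.
#'
#' @param siconc a `siconc` [grid_field()] covering Southern Ocean
#'   latitudes.
#' @param month month of year (1-12).
#' @param year optional year; if omitted, all instances of `month` in the
#'   field are averaged first.
#' @param threshold concentration threshold, percent (15 = extent contour).
#' @return An `ice_edge`: data.frame `lon`, `edge_lat` with `month`,
#'   `period`, `threshold` attributes.
#' @export
extract_ice_edge <- function(siconc, month, year = NULL, threshold = 15) {
  stopifnot(inherits(siconc, "grid_field"))
  if (max(siconc$lat) > -30)
    warning("field extends north of 30 S; edge extraction assumes a ",
            "Southern Ocean context")
  idx <- time_index(siconc,
                    years = if (is.null(year)) NULL else c(year, year),
                    months = month)
  if (!length(idx)) stop("no time steps match the requested month/year")
  conc <- apply(siconc$values[idx, , , drop = FALSE], c(2, 3), mean)
  edge <- .edge_from_matrix(conc, siconc$lat, siconc$lon, threshold)
  period <- if (is.null(year)) range(siconc$time$year[idx]) else c(year, year)
  structure(data.frame(lon = siconc$lon, edge_lat = edge),
            month = month, period = period, threshold = threshold,
            class = c("ice_edge", "data.frame"))
}

#' Decadal mean sea-ice edges by month
#'
#' For each austral-summer month, averages the concentration field over the
#' decade's instances of that month and extracts the edge of the mean field
#' (mean-then-edge, asserted by a regression test on a linearly retreating
#' field; this differs from the mean of yearly edges when the retreat
#' interacts with the logistic profile).
#'
#' @param siconc a `siconc` [grid_field()].
#' @param decade year range `c(first, last)`.
#' @param months months of year, default October-March.
#' @param threshold concentration threshold, percent.
#' @return Named list of `ice_edge` objects, one per month.
#' @export
decadal_mean_edge <- function(siconc, decade, months = c(10:12, 1:3),
                              threshold = 15) {
  stopifnot(decade[2] >= decade[1])
  if (!length(time_index(siconc, years = decade)))
    stop("decade not covered by the field")
  out <- lapply(months, function(m) {
    idx <- time_index(siconc, years = decade, months = m)
    if (!length(idx)) return(NULL)
    conc <- apply(siconc$values[idx, , , drop = FALSE], c(2, 3), mean)
    structure(data.frame(lon = siconc$lon,
                         edge_lat = .edge_from_matrix(conc, siconc$lat,
                                                      siconc$lon, threshold)),
              month = m, period = decade, threshold = threshold,
              class = c("ice_edge", "data.frame"))
  })
  names(out) <- sprintf("month%02d", months)
  out[!vapply(out, is.null, logical(1))]
}

#' Mean NPP along the sea-ice edge sector
#'
#' Averages NPP over the cells within `band` degrees latitude of the edge,
#' per longitude across the sector (60 W-120 E by default, the sector where
#' terns forage at the edge), then across longitudes.
#'
#' @param intpp an `intpp` [grid_field()] or [grid_slice()] on the same
#'   grid as the edge.
#' @param edge an `ice_edge`.
#' @param sector longitude range `c(west, east)`.
#' @param band half-width of the latitude band around the edge, degrees.
#' @param year,month time selection when `intpp` is a full field; defaults
#'   to the edge's month over the edge's period.
#' @return Mean NPP in the edge band (scalar; `NA` if the edge is fully
#'   missing in the sector).
#' @export
edge_sector_npp <- function(intpp, edge, sector = c(-60, 120), band = 2,
                            year = NULL, month = NULL) {
  stopifnot(inherits(edge, "ice_edge"))
  if (inherits(intpp, "grid_field")) {
    if (is.null(month)) month <- attr(edge, "month")
    yrs <- if (is.null(year)) attr(edge, "period") else c(year, year)
    idx <- time_index(intpp, years = yrs,
                      months = if (all(is.na(intpp$time$month))) NULL else month)
    if (!length(idx)) stop("no NPP time steps match the edge period")
    npp <- apply(intpp$values[idx, , , drop = FALSE], c(2, 3), mean)
    lat <- intpp$lat; lon <- intpp$lon
  } else {
    npp <- intpp$values; lat <- intpp$lat; lon <- intpp$lon
  }
  if (!isTRUE(all.equal(lon, edge$lon)))
    stop("edge and NPP must share the longitude grid")
  lo <- sector[1]; hi <- sector[2]
  in_sec <- if (lo <= hi) lon >= lo & lon <= hi else lon >= lo | lon <= hi
  vals <- rep(NA_real_, length(lon))
  for (j in which(in_sec)) {
    e <- edge$edge_lat[j]
    if (!is.finite(e)) next
    sel <- abs(lat - e) <= band
    if (!any(sel)) next
    vals[j] <- mean(npp[sel, j], na.rm = TRUE)
  }
  if (all(!is.finite(vals[in_sec]))) return(NA_real_)
  mean(vals[in_sec], na.rm = TRUE)
}

#' Distance of tracking fixes to the sea-ice edge
#'
#' Great-circle distance from each austral-summer fix south of 40 S to the
#' edge latitude at the fix's longitude (same-longitude meridian arc).
#'
#' @param tracks a `track_set`.
#' @param edge an `ice_edge`.
#' @param months months of year to include, default October-March.
#' @return `list(median_km, q25_km, q75_km, n, n_skipped)`; fixes at
#'   longitudes with no edge are skipped and counted.
#' @export
edge_association <- function(tracks, edge, months = c(10:12, 1:3)) {
  stopifnot(inherits(tracks, "track_set"), inherits(edge, "ice_edge"))
  mo <- as.integer(strftime(tracks$timestamp, "%m", tz = "UTC"))
  sel <- tracks$lat < -40 & mo %in% months
  fx <- tracks[sel, , drop = FALSE]
  if (!nrow(fx)) stop("no austral-summer fixes south of 40 S")
  j <- match(.cell_floor(.wrap_lon(fx$lon)) + 0.5, edge$lon)
  e <- edge$edge_lat[j]
  ok <- !is.na(j) & is.finite(e)
  d_km <- geosphere::distHaversine(cbind(fx$lon[ok], fx$lat[ok]),
                                   cbind(fx$lon[ok], e[ok]),
                                   r = 6371000) / 1000
  q <- stats::quantile(d_km, c(0.25, 0.5, 0.75), names = FALSE)
  list(median_km = q[2], q25_km = q[1], q75_km = q[3],
       n = sum(ok), n_skipped = sum(!ok))
}
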