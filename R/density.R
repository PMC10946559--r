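# Tracking fixes -> 1-degree tern-day density surface and per-region
# weights. The density surface identifies key stopover areas and weights
# regional NPP so that emergence statistics reflect the cells terns
# actually use.

#' A rectangular lat-lon region box
#'
#' @param name region label.
#' @param lat_range `c(south, north)` bounds, degrees.
#' @param lon_range `c(west, east)` bounds, degrees; `west > east` denotes
#'   an antimeridian-wrapping box.
#' @return A list of class `region_box`.
#' @export
region_box <- function(name, lat_range, lon_range) {
  stopifnot(lat_range[1] < lat_range[2])
  structure(list(name = name, lat_range = lat_range, lon_range = lon_range),
            class = "region_box")
}

#' The four key tern stopover/overwinter regions
#'
#' North Atlantic subpolar gyre (40-65 N, 60 W-0), Benguela upwelling
#' (40 S-0, 10 W-30 E), Subantarctic Indian Ocean around Amsterdam Island
#' (55-20 S, 50-100 E), and the greater Southern Ocean (poleward of 55 S).
#'
#' @return Named list of [region_box()]es.
#' @export
tern_regions <- function() {
  list(
    north_atlantic = region_box("north_atlantic", c(40, 65), c(-60, 0)),
    benguela = region_box("benguela", c(-40, 0), c(-10, 30)),
    subantarctic_indian = region_box("subantarctic_indian", c(-55, -20), c(50, 100)),
    southern_ocean = region_box("southern_ocean", c(-90, -55), c(-180, 180))
  )
}

#' Membership of grid-cell centres in a region box (wrap-aware)
#'
#' @param box a [region_box()].
#' @param lat,lon cell-centre coordinate vectors.
#' @return Logical matrix `length(lat)` x `length(lon)`.
#' @export
in_region <- function(box, lat, lon) {
  in_lat <- lat >= box$lat_range[1] & lat <= box$lat_range[2]
  lo <- box$lon_range[1]; hi <- box$lon_range[2]
  in_lon <- if (lo <= hi) lon >= lo & lon <= hi else lon >= lo | lon <= hi
  outer(in_lat, in_lon, FUN = "&")
}

#' Bin tracking fixes into 1-degree tern-days
#'
#' Each fix contributes the elapsed time to the bird's next fix, assigned to
#' the fix's cell (half-open time-to-next attribution). Gaps longer than
#' `gap_cap` times the device's nominal interval are capped at the cap
#' (equinox gaps and 24-h-daylight gaps are not interpolated). The final fix
#' of each bird, and a single-fix bird, contribute one nominal interval.
#'
#' @param tracks a `track_set` (see [as_track_set()]).
#' @param lat_range,lon_range grid edges; cells are `[i, i+1)` degrees.
#' @param gap_cap cap multiplier on the nominal interval.
#' @return A `density_grid`: matrix of tern-days `length(lat)` x
#'   `length(lon)` with cell-centre `lat`/`lon`, `smoothed` and
#'   `smoothing_sigma` attributes.
#' @export
bin_tern_days <- function(tracks, lat_range = c(-90, 90),
                          lon_range = c(-180, 180), gap_cap = 2) {
  stopifnot(inherits(tracks, "track_set"), nrow(tracks) >= 1)
  nominal <- attr(tracks, "nominal_interval_h")
  lat <- .centres(lat_range); lon <- .centres(lon_range)
  dens <- matrix(0, length(lat), length(lon))

  for (b in unique(tracks$bird_id)) {
    tb <- tracks[tracks$bird_id == b, , drop = FALSE]
    nom_d <- nominal[[tb$device[1]]] / 24
    tt <- as.numeric(tb$timestamp) / 86400
    dt <- c(diff(tt), nom_d)                 # final fix: nominal interval
    dt <- pmin(dt, gap_cap * nom_d)
    i <- match(.cell_floor(tb$lat) + 0.5, lat)
    j <- match(.cell_floor(.wrap_lon(tb$lon)) + 0.5, lon)
    ok <- !is.na(i) & !is.na(j)
    for (k in which(ok)) dens[i[k], j[k]] <- dens[i[k], j[k]] + dt[k]
  }
  structure(dens, lat = lat, lon = lon, smoothed = FALSE,
            smoothing_sigma = 0, class = "density_grid")
}

#' Gaussian-smooth a density grid (mass conserving)
#'
#' Separable truncated Gaussian kernel (radius 4 sigma in cells), applied as
#' a mass redistribution: each source cell's kernel is renormalised over the
#' part of its footprint that falls inside the grid, so the global sum is
#' conserved exactly, including at grid edges. `sigma = 0` is the identity.
#'
#' @param density a `density_grid` from [bin_tern_days()].
#' @param sigma kernel SD in cells.
#' @return A smoothed `density_grid`.
#' @export
smooth_density <- function(density, sigma = 1) {
  stopifnot(inherits(density, "density_grid"))
  if (sigma < 0) stop("negative sigma rejected")
  if (sigma == 0) return(density)
  r <- ceiling(4 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)

  pass <- function(m) {       # smooth down columns (i.e. along rows axis)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (off in -r:r) {
      src <- seq_len(n)
      dst <- src + off
      keep <- dst >= 1 & dst <= n
      # per-source renormalisation: kernel mass inside the grid
      norm <- .edge_norm(n, r, k)
      out[dst[keep], ] <- out[dst[keep], ] +
        m[src[keep], , drop = FALSE] * (k[off + r + 1] / norm[src[keep]])
    }
    out
  }
  sm <- t(pass(t(pass(unclass(density)))))
  structure(sm, lat = attr(density, "lat"), lon = attr(density, "lon"),
            smoothed = TRUE, smoothing_sigma = sigma, class = "density_grid")
}

# kernel mass that stays inside a length-n axis for each source index
#' @keywords internal
.edge_norm <- function(n, r, k) {
  norm <- numeric(n)
  for (s in seq_len(n)) {
    off <- max(-r, 1 - s):min(r, n - s)
    norm[s] <- sum(k[off + r + 1])
  }
  norm
}

#' Tern-density weights for a region
#'
#' Weights are the tern-days of the cells inside the box, normalised to sum
#' to one. A region with zero density gets uniform weights (with a warning),
#' so an unweighted regional mean is the graceful fallback.
#'
#' @param density a `density_grid`.
#' @param region a [region_box()].
#' @return A `region_weights` object: weight matrix over the density grid
#'   (zero outside the box, summing to 1 inside) with `lat`/`lon`/`region`
#'   attributes.
#' @export
region_weights <- function(density, region) {
  stopifnot(inherits(density, "density_grid"), inherits(region, "region_box"))
  lat <- attr(density, "lat"); lon <- attr(density, "lon")
  inb <- in_region(region, lat, lon)
  if (!any(inb)) stop("region does not intersect the density grid")
  w <- matrix(0, length(lat), length(lon))
  tot <- sum(density[inb])
  if (tot > 0) {
    w[inb] <- density[inb] / tot
  } else {
    warning("zero tern-days in region '", region$name,
            "'; using uniform weights")
    w[inb] <- 1 / sum(inb)
  }
  structure(w, lat = lat, lon = lon, region = region$name,
            class = "region_weights")
}
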