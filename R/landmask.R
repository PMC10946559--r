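# Coarse 1-degree land mask from hand-digitised continental outlines.
# This is a deliberately coarse synthetic stand-in for a coastline product:
# it resolves continents at the few-degree level, which is all the analyses
# here need (Africa-crossing flags, plotting context). Antarctica is handled
# by rule (latitude bands with a Weddell Sea embayment and the Peninsula)
# because a polygon at the pole is awkward on a lon-lat grid.

#' @keywords internal
coarse_land_polygons <- function() {
  list(
    africa = cbind(
      lon = c(-9.5, -6, 3, 10.5, 20, 32, 34.5, 37, 43, 51.5, 46, 40.5, 36,
              33, 27, 20, 17.5, 15, 12, 13.5, 9.5, 9, 5, -4, -8, -13, -17,
              -16.5, -13, -9.5),
      lat = c(32, 35.5, 37, 37.5, 32.5, 31.5, 28, 21, 11.5, 11.5, -1, -11,
              -18, -26, -33.5, -34.8, -33, -27, -18, -11, -2, 4, 6, 5.2,
              4.5, 9, 14.5, 20, 25, 32)),
    madagascar = cbind(
      lon = c(44, 47, 50, 49, 47, 44, 43, 44),
      lat = c(-25, -25, -16, -12, -15, -20, -23, -25)),
    south_america = cbind(
      lon = c(-62, -72, -78, -80, -76, -70.5, -71.5, -73.5, -74, -69, -66,
              -68, -65, -62, -58, -53, -48, -41, -38.5, -35, -35, -44, -50,
              -52, -60, -62),
      lat = c(10.5, 11.5, 8, -3, -14, -18.5, -30, -43, -50, -55, -55, -50,
              -41, -39, -34, -34, -26, -23, -13, -9, -5.5, -2.5, 0, 4, 8.5,
              10.5)),
    central_america = cbind(
      lon = c(-92, -84, -78, -80, -83, -88, -92),
      lat = c(18, 11, 8, 4, 8, 13, 18)),
    north_america = cbind(
      lon = c(-105, -97, -90, -84, -81, -80, -76, -70, -60, -55, -60, -78,
              -85, -95, -110, -125, -130, -125, -117, -110, -105),
      lat = c(20, 26, 30, 30, 25, 27, 35, 42, 46, 52, 55, 58, 66, 70, 70,
              70, 55, 40, 33, 23, 20)),
    greenland = cbind(
      lon = c(-45, -40, -32, -25, -20, -18, -22, -32, -45, -55, -60, -55,
              -53, -48, -45),
      lat = c(60, 64, 68, 70, 70, 75, 78, 82, 82, 82, 76, 70, 66, 61, 60)),
    eurasia = cbind(
      lon = c(-10, -9, -1, -5, 1, 7, 8, 10, 18, 25, 28, 25, 20, 30, 60, 90,
              110, 140, 160, 179, 179, 160, 155, 140, 130, 127, 122, 108,
              105, 100, 98, 92, 88, 80, 77, 72, 66, 57, 59, 53, 44, 48, 52,
              48, 35, 33, 36, 30, 26, 22, 18, 15, 12, 8, 3, -2, -6, -10),
      lat = c(36, 43, 44, 48, 51, 54, 57, 59, 56, 57, 60, 65, 69, 70, 69,
              73, 73, 72, 70, 66, 64, 60, 50, 45, 42, 38, 30, 18, 9, 6, 8,
              15, 21, 15, 8, 20, 24, 25, 22, 15, 12, 29, 28, 29, 27, 28, 36,
              41, 40, 37, 40, 40, 44, 44, 43, 36, 36, 36)),
    australia = cbind(
      lon = c(114, 113, 115, 124, 130, 136, 140, 147, 150, 153, 153, 146,
              142, 136, 131, 126, 122, 114),
      lat = c(-22, -26, -35, -33, -32, -35, -38, -39, -37, -32, -25, -19,
              -11, -12, -12, -14, -18, -22))
  )
}

#' Coarse land mask on a 1-degree grid
#'
#' Boolean land/ocean mask at 1-degree cell centres, built from coarse
#' continental outlines plus a rule-based Antarctica (ice-sheet land south
#' of 75 S, coastline at 70 S outside the Weddell Sea embayment, and the
#' Antarctic Peninsula). Synthetic/coarse by construction; suitable for
#' continental-scale queries such as Africa-crossing flags, not for
#' coastline work.
#'
#' @param lat,lon cell-centre coordinate vectors (e.g. `seq(-89.5, 89.5)`).
#' @return Logical matrix `length(lat)` x `length(lon)`, `TRUE` over land,
#'   with `lat`/`lon` attached as attributes.
#' @export
land_mask_1deg <- function(lat = seq(-89.5, 89.5, by = 1),
                           lon = seq(-179.5, 179.5, by = 1)) {
  pts <- expand.grid(lat = lat, lon = lon)  # lat varies fastest = row-major fill
  land <- rep(FALSE, nrow(pts))
  for (poly in coarse_land_polygons()) {
    land <- land | pracma::inpolygon(pts$lon, pts$lat,
                                     poly[, "lon"], poly[, "lat"])
  }
  # Antarctica by rule: Weddell Sea reaches south of 70 S between 63 W and 10 W
  land <- land |
    pts$lat <= -75 |
    (pts$lat <= -70 & !(pts$lon > -63 & pts$lon < -10)) |
    (pts$lat <= -64 & pts$lon >= -65 & pts$lon <= -56)
  m <- matrix(land, nrow = length(lat), ncol = length(lon))
  attr(m, "lat") <- lat
  attr(m, "lon") <- lon
  m
}
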