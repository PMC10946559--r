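# Plain-text interchange: tracking CSV (bird_id, ISO-8601 UTC timestamp,
# lat, lon, device), long-format gridded-field CSV with a metadata header,
# and ice-edge CSV.

#' Write / read tracking fixes as CSV
#'
#' Columns: `bird_id`, `timestamp` (ISO-8601 UTC), `lat`, `lon`, `device`.
#' Writing is deterministic, so a fixed generator seed yields a
#' byte-identical file.
#'
#' @param tracks a `track_set`.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  out <- data.frame(
    bird_id = tracks$bird_id,
    timestamp = strftime(tracks$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = sprintf("%.6f", tracks$lat),
    lon = sprintf("%.6f", tracks$lon),
    device = tracks$device
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  as_track_set(x)
}

#' Write / read a gridded field as long-format CSV
#'
#' Metadata (`variable`, `units`) travel in `#`-prefixed header lines;
#' data columns are `year`, `month`, `doy`, `lat`, `lon`, `value`.
#' A plain-text stand-in for gridded binary formats, adequate at the
#' problem sizes this package targets.
#'
#' @param field a [grid_field()].
#' @param path file path.
#' @export
write_grid_csv <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# variable: ", field$variable),
               paste0("# units: ", field$units)), con)
  nt <- nrow(field$time)
  df <- data.frame(
    year = rep(field$time$year, times = length(field$lat) * length(field$lon)),
    month = rep(field$time$month, times = length(field$lat) * length(field$lon)),
    doy = rep(field$time$doy, times = length(field$lat) * length(field$lon)),
    lat = rep(rep(field$lat, each = nt), times = length(field$lon)),
    lon = rep(field$lon, each = nt * length(field$lat)),
    value = as.vector(field$values)
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  variable <- sub("^# variable: ", "", hdr[1])
  units <- sub("^# units: ", "", hdr[2])
  df <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  time <- unique(df[c("year", "month", "doy")])
  rownames(time) <- NULL
  nt <- nrow(time)
  df <- df[order(df$lon, df$lat, df$year,
                 ifelse(is.na(df$month), 0L, df$month),
                 ifelse(is.na(df$doy), 0L, df$doy)), ]
  vals <- array(df$value, c(nt, length(lat), length(lon)))
  grid_field(variable, vals, units, time, lat, lon)
}

#' Write an ice edge as CSV (lon, edge_lat, month, first/last period year)
#'
#' @param edge an `ice_edge`.
#' @param path file path.
#' @export
write_edge_csv <- function(edge, path) {
  stopifnot(inherits(edge, "ice_edge"))
  per <- attr(edge, "period")
  out <- data.frame(lon = edge$lon, edge_lat = edge$edge_lat,
                    month = attr(edge, "month"),
                    period_first = per[1], period_last = per[2])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
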