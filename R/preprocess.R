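#' Read a raw ping file
#'
#' Expects headered delimited text with columns `ad_id`, `unix_timestamp`,
#' `lat`, `lon`, `accuracy_m` (extra columns are carried along). Column
#' names are mapped onto the internal schema `device_id`, `t`, `lat`, `lon`,
#' `accuracy`.
#'
#' @param path file path (anything [data.table::fread()] accepts).
#' @return a data.table of raw pings.
#' @export
read_pings <- function(path) {
  dt <- data.table::fread(path)
  map <- c(ad_id = "device_id", unix_timestamp = "t", accuracy_m = "accuracy",
           timestamp = "t")
  for (nm in names(map)) {
    if (nm %in% names(dt)) data.table::setnames(dt, nm, map[[nm]])
  }
  dt
}

#' Write pings in the exchange dialect
#' @param pings data.table with `device_id`, `t`, `lat`, `lon`, `accuracy`.
#' @param path output path.
#' @export
write_pings <- function(pings, path) {
  out <- data.table(ad_id = pings$device_id, unix_timestamp = pings$t,
                    lat = pings$lat, lon = pings$lon,
                    accuracy_m = pings$accuracy)
  data.table::fwrite(out, path)
  invisible(path)
}

GENERIC_AD_ID <- "00000000-0000-0000-0000-000000000000"

#' Standardize a raw ping stream
#'
#' Reproduces the panel-standardization contract: device ids are uppercased
#' and the all-zero generic id is dropped; records outside the study bounding
#' box are dropped; per device, coordinates are averaged within consecutive
#' 5-minute bins anchored at the unix epoch (`bin = floor(t / 300)`), one
#' output record per occupied bin at the bin-start timestamp; local calendar
#' fields are derived at a fixed UTC offset (no DST). Malformed rows (missing
#' or non-finite required fields, out-of-range coordinates) are dropped and
#' counted.
#'
#' The operation is idempotent: applying it to its own output is a no-op.
#' Removal counts are reported in the `"log"` attribute.
#'
#' @param pings data.table with columns `device_id`, `t` (unix seconds),
#'   `lat`, `lon` and optionally `accuracy`.
#' @param bbox optional `c(lon_min, lon_max, lat_min, lat_max)`; records
#'   outside it are dropped.
#' @param tz_offset fixed offset from UTC in hours used to derive local
#'   calendar fields (default -5).
#' @param bin_seconds averaging bin width in seconds (default 300).
#' @return data.table with `device_id`, `t` (bin start, unix), `lat`, `lon`,
#'   `accuracy`, `local_date`, `local_hour` (fractional), `day_bin`
#'   (5-minute bin of the local day, 0-287); attribute `"log"` holds removal
#'   counts.
#' @export
standardize_pings <- function(pings, bbox = NULL, tz_offset = -5,
                              bin_seconds = 300) {
  dt <- as.data.table(pings)
  if (!"accuracy" %in% names(dt)) dt[, accuracy := NA_real_]
  n_in <- nrow(dt)
  log <- list(n_in = n_in, n_malformed = 0L, n_generic_id = 0L,
              n_outside_bbox = 0L)
  if (n_in == 0L) {
    out <- dt[0, .(device_id, t, lat, lon, accuracy)]
    out <- .localize(out, tz_offset)
    setattr(out, "log", log)
    return(out)
  }

  ok <- !is.na(dt$device_id) & is.finite(dt$t) &
    is.finite(dt$lat) & is.finite(dt$lon) &
    dt$lat >= -90 & dt$lat <= 90 & dt$lon >= -180 & dt$lon <= 180
  log$n_malformed <- sum(!ok)
  dt <- dt[ok]

  dt[, device_id := toupper(device_id)]
  generic <- dt$device_id == GENERIC_AD_ID
  log$n_generic_id <- sum(generic)
  dt <- dt[!generic]

  if (!is.null(bbox)) {
    inside <- dt$lon >= bbox[1] & dt$lon <= bbox[2] &
      dt$lat >= bbox[3] & dt$lat <= bbox[4]
    log$n_outside_bbox <- sum(!inside)
    dt <- dt[inside]
  }

  dt[, bin := floor(t / bin_seconds)]
  out <- dt[, .(t = bin[1] * bin_seconds,
                lat = mean(lat), lon = mean(lon),
                accuracy = mean(accuracy)),
            by = .(device_id, bin)][, bin := NULL][]
  out <- .localize(out, tz_offset)
  setattr(out, "log", log)
  out[]
}

## derive local calendar fields at a fixed UTC offset
.localize <- function(dt, tz_offset) {
  local <- dt$t + tz_offset * 3600
  dt[, local_date := as.Date(floor(local / 86400), origin = "1970-01-01")]
  dt[, local_hour := (local %% 86400) / 3600]
  dt[, day_bin := as.integer(floor((local %% 86400) / 300))]
  dt
}

#' Remove pings near roads
#'
#' Drops pings within `buffer_m` of any road feature (LineStrings from a
#' GeoJSON layer), so vehicular traffic does not masquerade as residential
#' activity. Distances are great-circle point-to-segment distances.
#'
#' @param pings standardized pings.
#' @param roads output of [read_geojson()] on a road layer, or `NULL`
#'   (pass-through with a warning).
#' @param buffer_m buffer around road features in metres (default 50).
#' @return filtered pings; attribute `"n_road_masked"` holds the removal
#'   count.
#' @export
mask_roads <- function(pings, roads, buffer_m = 50) {
  dt <- as.data.table(pings)
  if (is.null(roads) || length(roads) == 0L) {
    warning("no road layer supplied; pings passed through unfiltered")
    setattr(dt, "n_road_masked", 0L)
    return(dt)
  }
  if (nrow(dt) == 0L) {
    setattr(dt, "n_road_masked", 0L)
    return(dt)
  }
  pts <- cbind(dt$lon, dt$lat)
  dmin <- rep(Inf, nrow(dt))
  for (f in roads) {
    for (line in f$rings) {
      d <- geosphere::dist2Line(pts, line)[, "distance"]
      dmin <- pmin(dmin, d)
    }
  }
  keep <- dmin > buffer_m
  out <- dt[keep]
  setattr(out, "n_road_masked", sum(!keep))
  out
}

#' Assign pings to grid cells
#'
#' Projects each ping into the grid's planar frame and tags it with
#' zero-based `(col, row)` indices using half-open cells, so a point exactly
#' on the shared edge of two cells lands in the higher-index cell.
#' Out-of-extent pings are excluded and counted.
#'
#' @param pings standardized pings.
#' @param grid a [grid_spec()].
#' @return pings with `col`, `row` columns; attribute `"n_out_of_extent"`
#'   counts exclusions.
#' @export
assign_grid <- function(pings, grid) {
  dt <- as.data.table(pings)
  xy <- grid_project(grid, dt$lon, dt$lat)
  dt[, col := as.integer(floor(xy$x / grid$cell_size))]
  dt[, row := as.integer(floor(xy$y / grid$cell_size))]
  inside <- dt$col >= 0L & dt$col < grid$n_cols &
    dt$row >= 0L & dt$row < grid$n_rows &
    xy$x >= 0 & xy$y >= 0
  out <- dt[inside]
  setattr(out, "n_out_of_extent", sum(!inside))
  out
}
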