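#' Planar analysis grid over a geographic bounding box
#'
#' Defines the ~1 km x 1 km neighborhood grid used throughout the pipeline.
#' Coordinates are projected into a local equirectangular frame anchored at
#' the south-west corner of the bounding box: metre-true at city scale, with
#' the metres-per-degree of longitude evaluated at the mid-latitude. Cells
#' are half-open intervals `[x0 + k*s, x0 + (k+1)*s)` so a point on the
#' shared edge of two cells belongs to the higher-index cell.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box in decimal degrees
#'   (WGS84).
#' @param cell_size cell edge in metres (default 1000).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size = 1000) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_size > 0)
  lat_mid <- (lat_min + lat_max) / 2
  g <- list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    cell_size = cell_size,
    m_per_deg_lat = 110540,
    m_per_deg_lon = 111320 * cos(lat_mid * pi / 180)
  )
  ## tiny slack so an extent that is an exact multiple of cell_size does not
  ## round up to a phantom column under floating-point error
  g$n_cols <- as.integer(ceiling((lon_max - lon_min) * g$m_per_deg_lon /
                                   cell_size - 1e-9))
  g$n_rows <- as.integer(ceiling((lat_max - lat_min) * g$m_per_deg_lat /
                                   cell_size - 1e-9))
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, %.0f m cells\n",
              x$n_cols, x$n_rows, x$cell_size))
  cat(sprintf("  lon [%.4f, %.4f]  lat [%.4f, %.4f]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Project lon/lat to local planar metres (and back)
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors.
#' @return `grid_project`: data.table with columns `x`, `y` in metres from the
#'   grid origin. `grid_unproject`: data.table with `lon`, `lat`.
#' @export
grid_project <- function(grid, lon, lat) {
  data.table(x = (lon - grid$lon_min) * grid$m_per_deg_lon,
             y = (lat - grid$lat_min) * grid$m_per_deg_lat)
}

#' @rdname grid_project
#' @param x,y planar metre coordinates.
#' @export
grid_unproject <- function(grid, x, y) {
  data.table(lon = grid$lon_min + x / grid$m_per_deg_lon,
             lat = grid$lat_min + y / grid$m_per_deg_lat)
}

#' Centre of a grid cell in lon/lat
#' @inheritParams grid_project
#' @param col,row zero-based cell indices.
#' @export
cell_center <- function(grid, col, row) {
  grid_unproject(grid,
                 (col + 0.5) * grid$cell_size,
                 (row + 0.5) * grid$cell_size)
}

#' Read a (minimal) GeoJSON file
#'
#' Supports FeatureCollections of Polygon, MultiPolygon and LineString
#' geometries, which covers the layers this pipeline consumes (county/state
#' boundaries, study extent, road lines). Returns a list of features, each
#' `list(properties = <list>, type = <chr>, rings = <list of Nx2 matrices>)`;
#' for LineStrings the single matrix is the line's coordinates.
#'
#' @param path file path.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  lapply(feats, function(f) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    coords <- geom$coordinates
    to_mat <- function(ring) {
      m <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
      colnames(m) <- c("lon", "lat")
      m
    }
    rings <- switch(geom$type,
      Polygon      = lapply(coords, to_mat),
      MultiPolygon = unlist(lapply(coords, function(p) lapply(p, to_mat)),
                            recursive = FALSE),
      LineString   = list(to_mat(coords)),
      stop("unsupported geometry type: ", geom$type)
    )
    list(properties = if (identical(f$type, "Feature")) f$properties else list(),
         type = geom$type, rings = rings)
  })
}

#' Write polygons to GeoJSON
#'
#' @param polys named list; each element a list of Nx2 lon/lat ring matrices
#'   (outer ring first) or a single matrix.
#' @param path output path.
#' @export
write_geojson <- function(polys, path) {
  feat <- lapply(names(polys), function(nm) {
    rings <- polys[[nm]]
    if (is.matrix(rings)) rings <- list(rings)
    coords <- lapply(rings, function(r) lapply(seq_len(nrow(r)),
                                               function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Point-in-polygon test
#'
#' Tests lon/lat points against the outer rings of one or more polygon
#' features (holes are ignored; none of the administrative layers used here
#' carry holes). Delegates the crossing test to [mgcv::in.out()].
#'
#' @param lon,lat point coordinate vectors.
#' @param features output of [read_geojson()], or a single ring matrix.
#' @return logical vector: inside any feature's outer ring.
#' @export
points_in_polygon <- function(lon, lat, features) {
  if (is.matrix(features)) features <- list(list(rings = list(features)))
  pts <- cbind(lon, lat)
  inside <- rep(FALSE, length(lon))
  for (f in features) {
    ring <- f$rings[[1]]
    ## in.out wants an open ring traversal; a closed ring works too
    inside <- inside | mgcv::in.out(ring, pts)
  }
  inside
}

#' Great-circle distance in miles
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @export
haversine_miles <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1609.344
}
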