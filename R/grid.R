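#' Behrmann equal-area projection (forward)
#'
#' Projects WGS84 longitude/latitude to the cylindrical equal-area projection
#' with standard parallel 30 degrees (Behrmann), on a sphere of radius
#' 6371.0088 km. The projection is exactly equal-area: a `e x e` km square in
#' projected space always covers the same spherical area.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @return a data.frame with columns `x`, `y` in kilometres.
#' @export
#' @examples
#' behrmann_project(0, 0)   # origin
behrmann_project <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  k <- cos(30 * pi / 180)
  data.frame(
    x = EARTH_RADIUS_KM * (lon * pi / 180) * k,
    y = EARTH_RADIUS_KM * sin(lat * pi / 180) / k
  )
}

#' Behrmann equal-area projection (inverse)
#'
#' @param x,y numeric vectors of projected coordinates in kilometres.
#' @return a data.frame with columns `lon`, `lat` in decimal degrees. `y`
#'   values beyond the poles yield `NA` latitude.
#' @export
behrmann_unproject <- function(x, y) {
  stopifnot(length(x) == length(y))
  k <- cos(30 * pi / 180)
  s <- y * k / EARTH_RADIUS_KM
  s[abs(s) > 1 + 1e-12] <- NA_real_
  s <- pmin(pmax(s, -1), 1)
  data.frame(
    lon = (x / (EARTH_RADIUS_KM * k)) * 180 / pi,
    lat = asin(s) * 180 / pi
  )
}

#' Build an equal-area grid
#'
#' Tessellates a longitude/latitude extent into square cells of side
#' `edge_km` in the Behrmann equal-area projection. Grid lines are anchored
#' at the projection's natural origin (0 E at the equator), so cell `(row,
#' col)` spans the half-open projected interval `[col*e, (col+1)*e) x
#' [row*e, (row+1)*e)`. Cell centroids are inverse-projected back to WGS84.
#'
#' @param edge_km cell edge length in km (default 250, a common macroecology
#'   grain).
#' @param extent numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @return an object of class `ea_grid`: list with `edge_km`, `extent`, and
#'   `cells` (data.frame: `cell`, `row`, `col`, `x0`, `x1`, `y0`, `y1`,
#'   `lon`, `lat`).
#' @export
#' @examples
#' g <- build_grid(250, c(-10, 10, -10, 10))
#' nrow(g$cells)
build_grid <- function(edge_km = 250, extent = c(-180, 180, -90, 90)) {
  stopifnot(is.numeric(edge_km), edge_km > 0, length(extent) == 4)
  if (extent[1] >= extent[2] || extent[3] >= extent[4])
    fail("degenerate extent: need lon_min < lon_max and lat_min < lat_max")
  extent[3:4] <- pmin(pmax(extent[3:4], -90), 90)
  p_lo <- behrmann_project(extent[1], extent[3])
  p_hi <- behrmann_project(extent[2], extent[4])
  # half-open cells: a cell is included if it overlaps the extent
  cols <- seq.int(floor(p_lo$x / edge_km), ceiling(p_hi$x / edge_km) - 1)
  rows <- seq.int(floor(p_lo$y / edge_km), ceiling(p_hi$y / edge_km) - 1)
  cells <- expand.grid(col = cols, row = rows, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("row", "col")]
  cells$x0 <- cells$col * edge_km
  cells$x1 <- cells$x0 + edge_km
  cells$y0 <- cells$row * edge_km
  cells$y1 <- cells$y0 + edge_km
  ctr <- behrmann_unproject(cells$x0 + edge_km / 2, cells$y0 + edge_km / 2)
  cells$lon <- ctr$lon
  cells$lat <- ctr$lat
  # drop cells whose centroid lies beyond the poles (unprojectable)
  cells <- cells[!is.na(cells$lat), , drop = FALSE]
  cells$cell <- sprintf("r%d_c%d", cells$row, cells$col)
  rownames(cells) <- cells$cell
  cells <- cells[, c("cell", "row", "col", "x0", "x1", "y0", "y1", "lon", "lat")]
  structure(list(edge_km = edge_km, extent = extent, cells = cells),
            class = "ea_grid")
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf("Equal-area grid (Behrmann): %d cells of %g x %g km\n",
              nrow(x$cells), x$edge_km, x$edge_km))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

# column-wrap period of a full 360-degree band: the 2*pi*R*cos(30) world
# width is generally not an integer number of cells, so the two partial
# columns flanking the antimeridian are treated as adjacent
grid_n_cols_world <- function(grid) {
  half <- pi * EARTH_RADIUS_KM * cos(30 * pi / 180)
  floor(half / grid$edge_km) - floor(-half / grid$edge_km) + 1
}

#' Assign records to grid cells
#'
#' Maps each record's coordinates to the unique half-open grid cell covering
#' its projected position. Records outside the grid's cell set get `NA` and
#' are counted in the `dropped` attribute.
#'
#' @param records data.frame with `decimalLongitude`, `decimalLatitude`.
#' @param grid an [build_grid()] object.
#' @return character vector of cell ids (one per record) with attribute
#'   `dropped` (count of records falling outside the grid).
#' @export
assign_records <- function(records, grid) {
  stopifnot(inherits(grid, "ea_grid"))
  p <- behrmann_project(records$decimalLongitude, records$decimalLatitude)
  id <- sprintf("r%d_c%d", floor(p$y / grid$edge_km), floor(p$x / grid$edge_km))
  id[!(id %in% grid$cells$cell)] <- NA_character_
  id[is.na(records$decimalLongitude) | is.na(records$decimalLatitude)] <- NA_character_
  structure(id, dropped = sum(is.na(id)))
}

#' Gridded raster container
#'
#' A minimal single-band raster: regular lon/lat sample points with a value
#' matrix. Used for bathymetry (elevation in metres, negative below sea
#' level) and sea-surface temperature fields.
#'
#' @param lon,lat increasing numeric vectors of sample coordinates (degrees).
#' @param values numeric matrix, `length(lat)` rows x `length(lon)` columns;
#'   `values[i, j]` is the value at `(lat[i], lon[j])`.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(lon, lat, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    fail("values must be length(lat) x length(lon)")
  if (is.unsorted(lon) || is.unsorted(lat))
    fail("lon and lat must be increasing")
  structure(list(lon = lon, lat = lat, values = values), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d samples, lon [%g, %g], lat [%g, %g]\n",
              length(x$lat), length(x$lon), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat)))
  cat(sprintf("  values: [%g, %g]\n", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Look up raster values at points (nearest sample)
#'
#' @param raster a [grid_raster()].
#' @param lon,lat query coordinates (degrees).
#' @return numeric vector of values; `NA` outside the raster's footprint.
#' @export
raster_lookup <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "grid_raster"))
  # nearest-neighbour indices
  nn <- function(grid_coords, q) {
    if (length(grid_coords) == 1) return(rep(1L, length(q)))
    round(stats::approx(grid_coords, seq_along(grid_coords), xout = q, rule = 2)$y)
  }
  i <- nn(raster$lat, lat)
  j <- nn(raster$lon, lon)
  out <- raster$values[cbind(i, j)]
  res_lat <- if (length(raster$lat) > 1) max(diff(raster$lat)) else Inf
  res_lon <- if (length(raster$lon) > 1) max(diff(raster$lon)) else Inf
  out[lat < min(raster$lat) - res_lat | lat > max(raster$lat) + res_lat |
      lon < min(raster$lon) - res_lon | lon > max(raster$lon) + res_lon] <- NA_real_
  out
}

#' Write / read a raster as plain gridded CSV
#'
#' The dependency-free on-disk raster format: first column `lat`, remaining
#' column names the longitudes, cells the values.
#'
#' @param raster a [grid_raster()].
#' @param path file path.
#' @return `read_raster_csv` returns a [grid_raster()]; `write_raster_csv`
#'   returns `path` invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  df <- data.frame(lat = raster$lat, raster$values, check.names = FALSE)
  names(df) <- c("lat", as.character(raster$lon))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid_raster(lon = as.numeric(names(df)[-1]), lat = df$lat,
              values = as.matrix(df[, -1, drop = FALSE]))
}

#' Identify shallow-water grid cells
#'
#' Keeps every grid cell containing at least one raster sample whose
#' elevation lies in the shallow band `[-depth_limit_m, 0)` metres (presence
#' rule: shelf cells are often partly deep, and a single shallow sample is
#' enough to admit shelf records).
#'
#' @param grid an [build_grid()] object.
#' @param bathymetry a [grid_raster()] of elevation in metres (negative below
#'   sea level).
#' @param depth_limit_m maximum depth in metres (default 200, the shelf
#'   break).
#' @return character vector of shallow cell ids.
#' @export
shallow_cell_mask <- function(grid, bathymetry, depth_limit_m = 200) {
  stopifnot(inherits(grid, "ea_grid"), inherits(bathymetry, "grid_raster"))
  pts <- expand.grid(lon = bathymetry$lon, lat = bathymetry$lat,
                     KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies lon fastest; values[i, j] is (lat i, lon j), so transpose
  v <- as.vector(t(bathymetry$values))
  shallow <- v < 0 & v >= -depth_limit_m
  if (!any(shallow)) return(character(0))
  p <- behrmann_project(pts$lon[shallow], pts$lat[shallow])
  id <- sprintf("r%d_c%d", floor(p$y / grid$edge_km), floor(p$x / grid$edge_km))
  intersect(grid$cells$cell, unique(id))
}

#' Export grid cells as GeoJSON
#'
#' Writes cell polygons (corners inverse-projected to WGS84) as a GeoJSON
#' FeatureCollection, optionally carrying per-cell properties.
#'
#' @param grid an [build_grid()] object.
#' @param path output file.
#' @param properties optional data.frame of extra per-cell properties, rows
#'   matching `grid$cells`.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, properties = NULL) {
  stopifnot(inherits(grid, "ea_grid"))
  cells <- grid$cells
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    corners <- behrmann_unproject(c(cc$x0, cc$x1, cc$x1, cc$x0, cc$x0),
                                  c(cc$y0, cc$y0, cc$y1, cc$y1, cc$y0))
    props <- list(cell = cc$cell, row = cc$row, col = cc$col)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, corners$lon, corners$lat))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
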