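# Grid, raster, polygon and point primitives shared by every other module.
#
# Conventions (fixed package-wide):
#  * cells are indexed row-major from the top-left corner;
#  * cell (r, c), 1-based, has its center at
#      (origin_x + (c - 0.5) * cell_size,  origin_y - (r - 0.5) * cell_size),
#    i.e. origin_(x,y) is the top-left corner of the grid;
#  * points exactly on a polygon boundary count as inside (closed-set rule);
#  * no-data is represented internally as NA.

#' Grid specification
#'
#' Describes the geometry shared by all aligned rasters: dimensions, top-left
#' origin, square cell size and a coordinate reference system identifier.
#' Two grids are aligned if and only if all fields are equal.
#'
#' @param n_rows,n_cols Positive integer dimensions.
#' @param origin_x,origin_y Map coordinates of the grid's top-left corner.
#' @param cell_size Positive cell edge length in map units.
#' @param crs_id Text CRS identifier. `"lonlat"` marks a geographic grid
#'   (degrees); `"ea_km"` marks a projected equal-area grid whose map unit is
#'   the kilometre (the synthetic-landscape default).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = n_rows * cell_size,
                      cell_size = 1, crs_id = "ea_km") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, is.character(crs_id))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), crs_id = crs_id),
    class = "grid_spec")
}

#' Test whether two grids are aligned (all fields equal)
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$crs_id == b$crs_id
}

#' Coordinates of all cell centers of a grid
#' @param grid A `grid_spec`.
#' @return A list with matrices/vectors `x` (length n_cols) and `y`
#'   (length n_rows), and `xy`, an (n_rows*n_cols) x 2 matrix in row-major
#'   cell order.
#' @export
cell_centers <- function(grid) {
  x <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  y <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  xy <- cbind(x = rep(x, times = grid$n_rows),
              y = rep(y, each = grid$n_cols))
  list(x = x, y = y, xy = xy)
}

#' Map coordinates to cell indices
#'
#' @param grid A `grid_spec`.
#' @param x,y Numeric coordinate vectors.
#' @return A data.frame with integer columns `row`, `col`; NA for points
#'   outside the grid extent. A point exactly on the shared edge of two cells
#'   belongs to the higher-index cell except on the outer right/bottom edge,
#'   which snaps inward so the extent is closed.
#' @export
cell_index <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  # closed outer boundary: snap the far edges inward
  col[x == grid$origin_x + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin_y - grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster layer
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix of dimension (n_rows, n_cols); `NA` is the
#'   no-data marker.
#' @param name Layer name.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values dimensions do not match the grid: expected ",
         grid$n_rows, "x", grid$n_cols)
  structure(list(grid = grid, values = values, name = name),
            class = "raster_layer")
}

#' Binary map (0/1/no-data raster)
#'
#' @param grid A `grid_spec`.
#' @param values Matrix over {0, 1, NA}.
#' @return An object of class `binary_map` (also a `raster_layer`).
#' @export
binary_map <- function(grid, values, name = "binary") {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("binary map values must be 0, 1 or NA")
  r <- raster_layer(grid, values, name)
  class(r) <- c("binary_map", class(r))
  r
}

#' Extract raster values at point locations
#' @param layer A `raster_layer`.
#' @param x,y Coordinate vectors.
#' @return Numeric vector; NA for points off the grid or on no-data cells.
#' @export
extract_values <- function(layer, x, y) {
  idx <- cell_index(layer$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

# ---- raster I/O: ESRI ASCII grid with a .prj sidecar for the CRS id -------

#' Write a raster layer as an ESRI ASCII grid
#'
#' Writes a plain-text `.asc` file (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header then rows top-to-bottom) plus a `.prj` sidecar holding
#' the CRS identifier.
#'
#' @param layer A `raster_layer`.
#' @param path Output path (extension `.asc` recommended).
#' @param nodata No-data value written to file in place of NA.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$origin_x, digits = 17)),
    paste("yllcorner", format(g$origin_y - g$n_rows * g$cell_size, digits = 17)),
    paste("cellsize", format(g$cell_size, digits = 17)),
    paste("NODATA_value", nodata)), con)
  vals <- layer$values
  vals[is.na(vals)] <- nodata
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  writeLines(g$crs_id, sub("\\.asc$", ".prj", path, ignore.case = TRUE))
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Path to a `.asc` file. A `.prj` sidecar, if present, supplies
#'   the CRS id (default `"unknown"`).
#' @param name Layer name; defaults to the file stem.
#' @return A `raster_layer` with NA at no-data cells.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  header <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    tolower(vapply(kv, `[`, character(1), 1)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header)))
    stop("not an ASCII grid (missing header fields): ", path)
  nodata <- if ("nodata_value" %in% names(header)) header[["nodata_value"]] else NA
  vals <- as.matrix(utils::read.table(path, skip = length(header)))
  dimnames(vals) <- NULL
  if (!all(dim(vals) == c(header[["nrows"]], header[["ncols"]])))
    stop("raster body dimensions disagree with header: ", path)
  if (!is.na(nodata)) vals[vals == nodata] <- NA
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  crs_id <- if (file.exists(prj)) readLines(prj, n = 1) else "unknown"
  grid <- grid_spec(header[["nrows"]], header[["ncols"]],
                    origin_x = header[["xllcorner"]],
                    origin_y = header[["yllcorner"]] +
                      header[["nrows"]] * header[["cellsize"]],
                    cell_size = header[["cellsize"]], crs_id = crs_id)
  raster_layer(grid, vals, name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- polygons --------------------------------------------------------------

#' Polygon set
#'
#' A list of polygons, each a list of closed rings (first = exterior,
#' rest = holes); a ring is a two-column coordinate matrix whose first and
#' last vertices coincide.
#'
#' @param polygons List of polygons as described above. A bare two-column
#'   matrix is promoted to a single exterior ring.
#' @param crs_id CRS identifier.
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(polygons, crs_id = "ea_km") {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2, nrow(ring) >= 4)
      if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ],
                            check.attributes = FALSE)))
        stop("polygon ring is not closed (first vertex must equal last)")
      unname(ring)
    })
  })
  structure(list(polygons = polygons, crs_id = crs_id), class = "polygon_set")
}

#' Axis-aligned rectangle as a polygon set
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @param crs_id CRS identifier.
#' @return A `polygon_set` with one rectangular polygon.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax, crs_id = "ea_km") {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  polygon_set(list(ring), crs_id = crs_id)
}

# points exactly on a ring edge (within tol) are flagged separately so the
# closed-set rule can override the even-odd crossing parity
.on_segment <- function(px, py, x1, y1, x2, y2, tol) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(abs(px - x1) <= tol & abs(py - y1) <= tol)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2 <= tol * tol
}

#' Point-in-polygon test (closed-set boundary rule)
#'
#' Even-odd ray casting over all rings (so holes are excluded), with points
#' on any ring boundary counting as inside.
#'
#' @param polys A `polygon_set`.
#' @param x,y Coordinate vectors.
#' @param tol Boundary tolerance in map units.
#' @return Logical vector: TRUE where the point is inside (or on the
#'   boundary of) any polygon of the set.
#' @export
points_in_polygons <- function(polys, x, y, tol = 1e-9) {
  stopifnot(inherits(polys, "polygon_set"), length(x) == length(y))
  n <- length(x)
  inside_any <- logical(n)
  for (poly in polys$polygons) {
    crossings <- integer(n)
    boundary <- logical(n)
    for (ring in poly) {
      nv <- nrow(ring) - 1L
      for (i in seq_len(nv)) {
        x1 <- ring[i, 1]; y1 <- ring[i, 2]
        x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
        boundary <- boundary | .on_segment(x, y, x1, y1, x2, y2, tol)
        # half-open edge rule [y1, y2) avoids double-counting vertices
        straddles <- (y1 > y) != (y2 > y)
        if (any(straddles)) {
          xi <- x1 + (y[straddles] - y1) / (y2 - y1) * (x2 - x1)
          hit <- which(straddles)[xi > x[straddles]]
          crossings[hit] <- crossings[hit] + 1L
        }
      }
    }
    inside_any <- inside_any | (crossings %% 2L == 1L) | boundary
  }
  inside_any
}

#' Rasterize polygons onto a grid (cell-center rule)
#'
#' A cell is 1 iff its center lies inside (or on the boundary of) any
#' polygon, else 0. No silent reprojection: the CRS ids must match.
#'
#' @param polys A `polygon_set`.
#' @param grid A `grid_spec` with the same `crs_id`.
#' @return A `binary_map` on `grid`.
#' @export
rasterize_polygons <- function(polys, grid) {
  stopifnot(inherits(polys, "polygon_set"), inherits(grid, "grid_spec"))
  if (polys$crs_id != grid$crs_id)
    stop("CRS mismatch: polygons are '", polys$crs_id, "', grid is '",
         grid$crs_id, "'")
  cc <- cell_centers(grid)
  inside <- points_in_polygons(polys, cc$xy[, 1], cc$xy[, 2])
  vals <- matrix(as.numeric(inside), grid$n_rows, grid$n_cols, byrow = TRUE)
  binary_map(grid, vals)
}

# ---- GeoJSON I/O -----------------------------------------------------------

#' Write a polygon set as GeoJSON
#' @param polys A `polygon_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(polys$polygons, function(poly) {
    list(type = "Feature", properties = list(),
         geometry = list(
           type = "Polygon",
           coordinates = lapply(poly, function(ring) {
             lapply(seq_len(nrow(ring)), function(i) ring[i, ])
           })))
  })
  obj <- list(type = "FeatureCollection", crs_id = polys$crs_id,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON file into a polygon set
#'
#' Accepts FeatureCollection, Feature, Polygon and MultiPolygon objects.
#' A non-standard top-level `crs_id` member (as written by
#' [write_polygons_geojson()]) is honoured; otherwise `crs_id` applies.
#'
#' @param path Path to a GeoJSON file.
#' @param crs_id Fallback CRS id when the file does not carry one.
#' @return A `polygon_set`.
#' @export
read_polygons_geojson <- function(path, crs_id = "lonlat") {
  if (!file.exists(path)) stop("cannot read GeoJSON: no such file: ", path)
  obj <- jsonlite::read_json(path)
  geoms <- switch(
    obj$type %||% "",
    FeatureCollection = lapply(obj$features, `[[`, "geometry"),
    Feature = list(obj$geometry),
    Polygon = ,
    MultiPolygon = list(obj),
    stop("unsupported GeoJSON type: ", obj$type %||% "<missing>"))
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  polys <- list()
  for (g in geoms) {
    coords <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    if (!g$type %in% c("Polygon", "MultiPolygon"))
      stop("unsupported geometry type: ", g$type)
    polys <- c(polys, lapply(coords, function(poly) lapply(poly, ring_mat)))
  }
  polygon_set(polys, crs_id = obj$crs_id %||% crs_id)
}

# ---- labelled points -------------------------------------------------------

#' Read labelled points from CSV (columns x, y, label)
#' @param path CSV path with header `x,y,label`.
#' @return A data.frame with numeric `x`, `y` and character `label`.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "label") %in% names(df)))
    stop("points CSV must have columns x, y, label")
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df
}

#' Write labelled points to CSV
#' @param points Data.frame with columns x, y, label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points[, c("x", "y", "label")], path, row.names = FALSE)
  invisible(path)
}

# ---- area ------------------------------------------------------------------

.EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius

#' Equal-area measurement of a binary map
#'
#' Sums per-cell areas over the 1-cells. On a projected equal-area grid
#' (`crs_id` starting with `"ea"`, map unit = km) each cell contributes
#' `cell_size^2` km². On a geographic grid (`crs_id == "lonlat"`) the exact
#' spherical cell area R^2 * dlon * (sin(lat_top) - sin(lat_bottom)) is used,
#' which is the cylindrical equal-area treatment evaluated analytically.
#'
#' @param map A `binary_map`.
#' @return A list with `area_km2` (area of the 1-cells) and `fraction`
#'   (area of 1-cells / area of all valid cells).
#' @export
equal_area_km2 <- function(map) {
  stopifnot(inherits(map, "binary_map"))
  g <- map$grid
  if (startsWith(g$crs_id, "ea")) {
    cell_area <- matrix(g$cell_size^2, g$n_rows, g$n_cols)
  } else if (g$crs_id == "lonlat") {
    lat_top <- g$origin_y - (seq_len(g$n_rows) - 1) * g$cell_size
    lat_bot <- lat_top - g$cell_size
    band <- .EARTH_RADIUS_KM^2 * (g$cell_size * pi / 180) *
      (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
    cell_area <- matrix(band, g$n_rows, g$n_cols)
  } else {
    stop("unknown CRS '", g$crs_id, "': cannot compute areas")
  }
  valid <- !is.na(map$values)
  if (!any(valid)) stop("map has no valid cells")
  a1 <- sum(cell_area[valid & map$values == 1])
  atot <- sum(cell_area[valid])
  list(area_km2 = a1, fraction = a1 / atot)
}
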