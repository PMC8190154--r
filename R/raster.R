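#' Daily NDVI raster stack
#'
#' Container for a dated sequence of co-registered NDVI grids on a regular
#' north-up grid. The geotransform follows the usual top-left convention:
#' `x = x_origin + col * pixel_size`, `y = y_origin - row * pixel_size`.
#'
#' @param dates Vector coercible to `Date`, one per grid.
#' @param grids A 3-D array `[rows, cols, dates]` or a list of equally
#'   shaped matrices. Values must lie in `[-1, 1]`.
#' @param geotransform List with `x_origin`, `y_origin` (map units of the
#'   top-left corner) and `pixel_size` (m). Defaults to a 3 m grid at the
#'   origin.
#' @return An object of class `ndvi_stack` with dates sorted ascending.
#' @export
ndvi_stack <- function(dates, grids,
                       geotransform = list(x_origin = 0,
                                           y_origin = NULL,
                                           pixel_size = 3)) {
  dates <- as.Date(dates)
  if (is.list(grids)) {
    dm <- dim(grids[[1]])
    if (!all(vapply(grids, function(g) identical(dim(g), dm), logical(1)))) {
      stop("ndvi_stack: all grids must share the same shape", call. = FALSE)
    }
    grids <- array(unlist(grids, use.names = FALSE), c(dm, length(grids)))
  }
  if (length(dim(grids)) != 3L || dim(grids)[3] != length(dates)) {
    stop("ndvi_stack: grids must be [rows, cols, n_dates]", call. = FALSE)
  }
  if (anyDuplicated(dates)) {
    stop("ndvi_stack: duplicated dates", call. = FALSE)
  }
  rng <- range(grids, na.rm = TRUE)
  if (rng[1] < -1 || rng[2] > 1) {
    stop("ndvi_stack: NDVI values must lie in [-1, 1]", call. = FALSE)
  }
  o <- order(dates)
  if (is.null(geotransform$y_origin)) {
    geotransform$y_origin <- dim(grids)[1] * geotransform$pixel_size
  }
  structure(list(dates = dates[o],
                 grids = grids[, , o, drop = FALSE],
                 geotransform = geotransform),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x$grids)
  cat(sprintf("NDVI stack: %d x %d pixels (%g m), %d dates (%s .. %s)\n",
              d[1], d[2], x$geotransform$pixel_size, d[3],
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

# ESRI ASCII grid writer; %.17g so IEEE doubles round-trip exactly.
write_ascii_grid <- function(grid, path, geotransform) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  px <- geotransform$pixel_size
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", geotransform$x_origin),
           sprintf("yllcorner %.17g", geotransform$y_origin - nr * px),
           sprintf("cellsize %.17g", px),
           "NODATA_value -9999")
  g <- grid
  g[is.na(g)] <- -9999
  rows <- apply(g, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(hdr, "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]])
  nr <- as.integer(vals[["nrows"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("read_ascii_grid: body size does not match header in ", path,
         call. = FALSE)
  }
  grid <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  grid[grid == vals[["nodata_value"]]] <- NA
  px <- vals[["cellsize"]]
  list(grid = grid,
       geotransform = list(x_origin = vals[["xllcorner"]],
                           y_origin = vals[["yllcorner"]] + nr * px,
                           pixel_size = px))
}

#' Write an NDVI stack as per-day ASCII grids
#'
#' One ESRI ASCII grid per date, named `ndvi_YYYY-MM-DD.asc`. Values are
#' written with enough digits that doubles round-trip bit-exactly.
#'
#' @param stack An [ndvi_stack()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_ndvi_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("ndvi_%s.asc", format(stack$dates)))
  for (i in seq_along(paths)) {
    write_ascii_grid(stack$grids[, , i], paths[i], stack$geotransform)
  }
  invisible(paths)
}

#' Read an NDVI stack from per-day ASCII grids
#'
#' @param paths Either a directory containing `ndvi_YYYY-MM-DD.asc` files
#'   or a character vector of such paths. Dates are parsed from the file
#'   names and the stack is returned date-sorted regardless of input order.
#' @return An [ndvi_stack()].
#' @export
read_ndvi_stack <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "^ndvi_\\d{4}-\\d{2}-\\d{2}\\.asc$",
                        full.names = TRUE)
  }
  if (length(paths) == 0L) {
    stop("read_ndvi_stack: no NDVI grids found", call. = FALSE)
  }
  dates <- as.Date(sub("^ndvi_(\\d{4}-\\d{2}-\\d{2})\\.asc$", "\\1",
                       basename(paths)))
  if (anyNA(dates)) {
    stop("read_ndvi_stack: cannot parse dates from file names", call. = FALSE)
  }
  parsed <- lapply(paths, read_ascii_grid)
  gt <- parsed[[1]]$geotransform
  same <- vapply(parsed, function(p) {
    identical(dim(p$grid), dim(parsed[[1]]$grid)) &&
      isTRUE(all.equal(p$geotransform, gt, tolerance = 0))
  }, logical(1))
  if (!all(same)) {
    stop("read_ndvi_stack: shape/geotransform mismatch across dates",
         call. = FALSE)
  }
  ndvi_stack(dates, lapply(parsed, `[[`, "grid"), gt)
}

#' Field boundary polygon
#'
#' A closed, non-self-intersecting ring in the raster's coordinate system.
#'
#' @param coords Two-column matrix of `(x, y)` vertices. The ring is closed
#'   automatically if the last vertex differs from the first.
#' @param site_id Label for the field.
#' @return Object of class `field_boundary`.
#' @export
field_boundary <- function(coords, site_id = "field") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 3L) {
    stop("field_boundary: need a two-column matrix of >= 3 vertices",
         call. = FALSE)
  }
  if (!all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- rbind(coords, coords[1, ])
  }
  n <- nrow(coords) - 1L
  x <- coords[, 1]; y <- coords[, 2]
  area <- abs(sum(x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n])) / 2
  if (area <= 0) stop("field_boundary: zero area", call. = FALSE)
  if (ring_self_intersects(coords)) {
    stop("field_boundary: ring is self-intersecting", call. = FALSE)
  }
  structure(list(site_id = site_id, coords = coords, area = area),
            class = "field_boundary")
}

# O(n^2) proper-crossing test between non-adjacent edges; fine for the
# vertex counts of field outlines.
ring_self_intersects <- function(coords) {
  n <- nrow(coords) - 1L
  if (n < 4L) return(FALSE)
  seg <- function(i) coords[c(i, i + 1L), , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  for (i in 1:(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure
      p <- seg(i); q <- seg(j)
      d1 <- cross(q[1, ], q[2, ], p[1, ])
      d2 <- cross(q[1, ], q[2, ], p[2, ])
      d3 <- cross(p[1, ], p[2, ], q[1, ])
      d4 <- cross(p[1, ], p[2, ], q[2, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Even-odd point-in-polygon test
#'
#' @param px,py Point coordinates (vectors of equal length).
#' @param boundary A [field_boundary()] (or a closed two-column matrix).
#' @return Logical vector; points exactly on an edge follow the ray-casting
#'   convention and are not guaranteed either way.
#' @export
point_in_polygon <- function(px, py, boundary) {
  coords <- if (inherits(boundary, "field_boundary")) boundary$coords
            else as.matrix(boundary)
  n <- nrow(coords) - 1L
  inside <- logical(length(px))
  xv <- coords[, 1]; yv <- coords[, 2]
  for (i in seq_len(n)) {
    x1 <- xv[i]; y1 <- yv[i]; x2 <- xv[i + 1L]; y2 <- yv[i + 1L]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Write a field boundary as GeoJSON
#'
#' @param boundary A [field_boundary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(boundary, path) {
  feature <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(site_id = boundary$site_id),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(boundary$coords)))
    ))
  )
  jsonlite::write_json(feature, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field boundary from GeoJSON
#'
#' Accepts a FeatureCollection (first feature used), a Feature, or a bare
#' Polygon geometry; only the exterior ring is kept.
#'
#' @param path Path to a GeoJSON file.
#' @return A [field_boundary()].
#' @export
read_boundary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_id <- "field"
  geom <- j
  if (identical(j$type, "FeatureCollection")) {
    feat <- if (is.data.frame(j$features)) {
      list(properties = j$features$properties[1, , drop = FALSE],
           geometry = list(type = j$features$geometry$type[1],
                           coordinates = j$features$geometry$coordinates[[1]]))
    } else j$features[[1]]
    if (!is.null(feat$properties$site_id)) {
      site_id <- as.character(unlist(feat$properties$site_id))[1]
    }
    geom <- feat$geometry
  } else if (identical(j$type, "Feature")) {
    if (!is.null(j$properties$site_id)) site_id <- j$properties$site_id
    geom <- j$geometry
  }
  if (!identical(unlist(geom$type), "Polygon")) {
    stop("read_boundary: expected a Polygon geometry", call. = FALSE)
  }
  ring <- geom$coordinates
  while (is.list(ring)) ring <- ring[[1]]
  if (length(dim(ring)) == 3L) ring <- ring[1, , ]
  field_boundary(ring, site_id)
}

#' Pixel-center coordinates of a grid
#'
#' @param nrow_,ncol_ Grid dimensions.
#' @param geotransform Geotransform list (see [ndvi_stack()]).
#' @return List of matrices `x`, `y` with the map coordinates of every
#'   pixel center.
#' @keywords internal
pixel_centers <- function(nrow_, ncol_, geotransform) {
  px <- geotransform$pixel_size
  x <- geotransform$x_origin + (seq_len(ncol_) - 0.5) * px
  y <- geotransform$y_origin - (seq_len(nrow_) - 0.5) * px
  list(x = matrix(x, nrow_, ncol_, byrow = TRUE),
       y = matrix(y, nrow_, ncol_))
}
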