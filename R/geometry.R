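# Terminus geometry: glacier-front polylines, fjord polygon, terminus buffers.
# All internal coordinates are projected metres (UTM); GeoJSON interchange is
# WGS84 lon/lat.

#' Terminus geometry container
#'
#' Holds the two glacier-front polylines, the fjord polygon, the terminus
#' buffer distance and the region areas used for the uniform-distribution
#' expectation. All coordinates are projected metres (UTM, northern
#' hemisphere).
#'
#' @param kronebreen two-column matrix (x, y) of the marine-terminating
#'   glacier front polyline, metres
#' @param kongsbreen two-column matrix (x, y) of the second front polyline
#' @param fjord two-column matrix (x, y) of the fjord polygon vertices
#'   (open ring; closed automatically)
#' @param buffer_distance near-terminus buffer in metres (default 500)
#' @param zone UTM zone of the coordinates
#' @param region_areas optional named vector of areas in km^2 with elements
#'   `kronebreen_near`, `kongsbreen_near`, `fjord`; computed by grid
#'   integration over the polygon when omitted
#' @param area_cell cell size (m) for the area integration grid
#' @return an object of class `terminus_geometry`
#' @export
terminus_geometry <- function(kronebreen, kongsbreen, fjord,
                              buffer_distance = 500, zone = 33,
                              region_areas = NULL, area_cell = 25) {
  kronebreen <- as.matrix(kronebreen); kongsbreen <- as.matrix(kongsbreen)
  fjord <- as.matrix(fjord)
  stopifnot(ncol(kronebreen) == 2, ncol(kongsbreen) == 2, ncol(fjord) == 2,
            nrow(kronebreen) >= 2, nrow(kongsbreen) >= 2, nrow(fjord) >= 3,
            buffer_distance > 0)
  g <- structure(list(kronebreen = unname(kronebreen),
                      kongsbreen = unname(kongsbreen),
                      fjord = unname(fjord),
                      buffer_distance = buffer_distance,
                      zone = zone),
                 class = "terminus_geometry")
  if (is.null(region_areas)) {
    region_areas <- compute_region_areas(g, cell = area_cell)
  }
  stopifnot(all(c("kronebreen_near", "kongsbreen_near", "fjord") %in%
                  names(region_areas)),
            all(region_areas > 0))
  g$region_areas <- region_areas
  g
}

#' @export
print.terminus_geometry <- function(x, ...) {
  cat("Terminus geometry (UTM zone", x$zone, ")\n")
  cat(sprintf("  buffer distance: %g m\n", x$buffer_distance))
  a <- x$region_areas
  cat(sprintf("  areas [km^2]: near Kronebreen %.2f, near Kongsbreen %.2f, fjord %.2f\n",
              a[["kronebreen_near"]], a[["kongsbreen_near"]], a[["fjord"]]))
  invisible(x)
}

# Minimum distance from each point (n x 2) to a polyline (m x 2 vertices).
dist_to_polyline <- function(pts, line) {
  pts <- rbind(pts)  # coerce vector to 1-row matrix
  n <- nrow(pts)
  d2 <- rep(Inf, n)
  for (i in seq_len(nrow(line) - 1)) {
    p1 <- line[i, ]; p2 <- line[i + 1, ]
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      t <- rep(0, n)
    } else {
      t <- ((pts[, 1] - p1[1]) * vx + (pts[, 2] - p1[2]) * vy) / len2
      t <- pmin(1, pmax(0, t))
    }
    dx <- pts[, 1] - (p1[1] + t * vx)
    dy <- pts[, 2] - (p1[2] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Point-in-polygon membership for projected points.
in_fjord <- function(pts, geometry) {
  pts <- rbind(pts)
  ring <- geometry$fjord
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  mgcv::in.out(ring, pts)
}

#' Region areas by grid integration
#'
#' Integrates the near-terminus buffers (clipped to the fjord polygon) and the
#' remaining fjord area on a regular grid of cell size `cell` metres.
#'
#' @param geometry a [terminus_geometry()] (region areas may be absent)
#' @param cell grid cell size in metres
#' @return named vector of areas in km^2 (`kronebreen_near`,
#'   `kongsbreen_near`, `fjord`)
#' @export
compute_region_areas <- function(geometry, cell = 25) {
  fj <- geometry$fjord
  xr <- range(fj[, 1]); yr <- range(fj[, 2])
  xs <- seq(xr[1] + cell / 2, xr[2], by = cell)
  ys <- seq(yr[1] + cell / 2, yr[2], by = cell)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- in_fjord(grid, geometry)
  grid <- grid[inside, , drop = FALSE]
  dkr <- dist_to_polyline(grid, geometry$kronebreen)
  dko <- dist_to_polyline(grid, geometry$kongsbreen)
  b <- geometry$buffer_distance
  near_kr <- dkr <= b & dkr <= dko
  near_ko <- dko <= b & !near_kr
  cell_km2 <- (cell / 1000)^2
  c(kronebreen_near = sum(near_kr) * cell_km2,
    kongsbreen_near = sum(near_ko) * cell_km2,
    fjord = sum(!near_kr & !near_ko) * cell_km2)
}

#' Synthetic fjord geometry
#'
#' A desk-scale stand-in for the inner-fjord study area: a rectangular fjord
#' polygon of about 46 km^2 whose west edge carries the marine-terminating
#' ("Kronebreen-like") front and whose north edge carries the second
#' ("Kongsbreen-like") front, dimensioned so the 500 m near-terminus regions
#' cover about 2.0 and 1.6 km^2 and the remaining fjord about 42.6 km^2.
#'
#' @param origin UTM (x, y) of the polygon's south-west corner
#' @param zone UTM zone
#' @param buffer_distance near-terminus buffer (m)
#' @return a [terminus_geometry()]
#' @export
synthetic_fjord_geometry <- function(origin = c(430000, 8750000), zone = 33,
                                     buffer_distance = 500) {
  ox <- origin[1]; oy <- origin[2]
  fjord <- cbind(c(0, 8720, 8720, 0), c(0, 0, 5300, 5300))
  kron <- cbind(c(0, 0), c(1000, 4215))
  kong <- cbind(c(2000, 4415), c(5300, 5300))
  shift <- function(m) cbind(m[, 1] + ox, m[, 2] + oy)
  terminus_geometry(shift(kron), shift(kong), shift(fjord),
                    buffer_distance = buffer_distance, zone = zone)
}

#' Write terminus geometry to GeoJSON
#'
#' Features are written in WGS84 lon/lat; buffer distance, UTM zone and region
#' areas are carried in feature/collection properties.
#'
#' @param geometry a [terminus_geometry()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_geometry_geojson <- function(geometry, path) {
  unproj <- function(m) {
    ll <- utm_unproject(m[, 1], m[, 2], zone = geometry$zone)
    lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1], ll[i, 2]))
  }
  ring <- geometry$fjord
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  feat <- function(name, type, coords) {
    list(type = "Feature",
         properties = list(name = name),
         geometry = list(type = type, coordinates = coords))
  }
  fc <- list(
    type = "FeatureCollection",
    properties = list(buffer_distance = geometry$buffer_distance,
                      utm_zone = geometry$zone,
                      region_areas = as.list(geometry$region_areas)),
    features = list(
      feat("kronebreen", "LineString", unproj(geometry$kronebreen)),
      feat("kongsbreen", "LineString", unproj(geometry$kongsbreen)),
      feat("fjord", "Polygon", list(unproj(ring)))
    )
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read terminus geometry from GeoJSON
#'
#' Expects the layout written by [write_geometry_geojson()]: LineString
#' features named `kronebreen` and `kongsbreen` plus a Polygon feature named
#' `fjord`, in WGS84 lon/lat. Coordinates are reprojected to UTM (zone from
#' the file, else from the centroid longitude).
#'
#' @param path GeoJSON file path
#' @return a [terminus_geometry()]
#' @export
read_geometry_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  names(feats) <- vapply(feats, function(f) f$properties$name, "")
  coords_mat <- function(cc) {
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  }
  kron_ll <- coords_mat(feats[["kronebreen"]]$geometry$coordinates)
  kong_ll <- coords_mat(feats[["kongsbreen"]]$geometry$coordinates)
  fj_ll <- coords_mat(feats[["fjord"]]$geometry$coordinates[[1]])
  # drop the GeoJSON ring-closing vertex
  if (all(abs(fj_ll[1, ] - fj_ll[nrow(fj_ll), ]) < 1e-9)) {
    fj_ll <- fj_ll[-nrow(fj_ll), , drop = FALSE]
  }
  zone <- fc$properties$utm_zone
  if (is.null(zone)) zone <- utm_zone_from_lon(mean(fj_ll[, 1]))
  proj <- function(ll) utm_project(ll[, 1], ll[, 2], zone = zone)
  buffer <- fc$properties$buffer_distance
  if (is.null(buffer)) buffer <- 500
  areas <- fc$properties$region_areas
  if (!is.null(areas)) areas <- unlist(areas)
  terminus_geometry(proj(kron_ll), proj(kong_ll), proj(fj_ll),
                    buffer_distance = buffer, zone = zone,
                    region_areas = areas)
}
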