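# Dive geolocation: interpolation between bracketing GPS fixes, glacier-region
# classification, region statistics and dive-density gridding. All distances
# are Euclidean in projected metres (error is negligible at fjord scale).

#' Interpolate a dive location from bracketing GPS fixes
#'
#' Position linear in time between the two fixes, in projected coordinates.
#' If the fixes coincide in time their (common) position is returned.
#'
#' @param fix_before,fix_after one-row data.frames (or lists) with `seal_id`,
#'   `time` (POSIXct), `x`, `y` (projected metres)
#' @param dive_time POSIXct time of the dive, within the bracket
#' @return list with `x`, `y` and `location_source = "interpolated"`
#' @export
interpolate_dive_location <- function(fix_before, fix_after, dive_time) {
  if (fix_before$seal_id != fix_after$seal_id) {
    stop("bracketing fixes belong to different seals")
  }
  t0 <- as.numeric(fix_before$time)
  t1 <- as.numeric(fix_after$time)
  td <- as.numeric(dive_time)
  if (t1 < t0) stop("fixes are out of order")
  if (td < t0 || td > t1) {
    stop("dive time lies outside the bracketing fixes")
  }
  w <- if (t1 == t0) 0 else (td - t0) / (t1 - t0)
  list(x = fix_before$x + w * (fix_after$x - fix_before$x),
       y = fix_before$y + w * (fix_after$y - fix_before$y),
       location_source = "interpolated")
}

#' Classify dive locations by glacier region
#'
#' A point within the terminus buffer of either front is assigned to that
#' front's near-terminus region (ties go to the nearer front, then to
#' Kronebreen); otherwise `fjord` if inside the fjord polygon, else
#' `outside`. Classification is total and deterministic.
#'
#' @param points two-column matrix (x, y) of projected coordinates (a single
#'   point may be given as a length-2 vector)
#' @param geometry a [terminus_geometry()]
#' @return character vector of labels: `kronebreen_near`, `kongsbreen_near`,
#'   `fjord`, `outside`
#' @export
classify_region <- function(points, geometry) {
  pts <- rbind(points)
  dkr <- dist_to_polyline(pts, geometry$kronebreen)
  dko <- dist_to_polyline(pts, geometry$kongsbreen)
  b <- geometry$buffer_distance
  lab <- rep("outside", nrow(pts))
  inside <- in_fjord(pts, geometry)
  lab[inside] <- "fjord"
  near_kr <- dkr <= b & dkr <= dko  # tie at equal distance -> Kronebreen
  near_ko <- dko <= b & !near_kr
  lab[near_kr] <- "kronebreen_near"
  lab[near_ko] <- "kongsbreen_near"
  lab
}

#' Region counts and percentages
#'
#' @param regions character vector of region labels (one per profile)
#' @return data.frame with `region`, `count`, `percent` (0.1% precision) and
#'   `percent_int` (integer rounding), ordered near-Kronebreen,
#'   near-Kongsbreen, fjord, outside (present regions only)
#' @export
region_percentages <- function(regions) {
  if (!length(regions)) stop("no classified profiles")
  lev <- c("kronebreen_near", "kongsbreen_near", "fjord", "outside")
  counts <- table(factor(regions, levels = lev))
  counts <- counts[counts > 0 | names(counts) != "outside"]
  total <- sum(counts)
  data.frame(region = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / total, 1),
             percent_int = as.integer(round(100 * as.integer(counts) / total)),
             row.names = NULL)
}

#' Expected near-terminus percentages under uniform diving
#'
#' The share of dives expected in each near-terminus region if dives were
#' uniformly distributed over the study area. The denominator is either the
#' fjord region alone or fjord plus both near-terminus buffers.
#'
#' @param geometry a [terminus_geometry()] with `region_areas` set
#' @param denominator `"total"` (fjord + buffers) or `"fjord"` (fjord region
#'   only)
#' @return named vector of expected percentages for `kronebreen_near` and
#'   `kongsbreen_near`
#' @export
uniform_expectation <- function(geometry, denominator = c("total", "fjord")) {
  denominator <- match.arg(denominator)
  a <- geometry$region_areas
  denom <- switch(denominator,
                  total = a[["kronebreen_near"]] + a[["kongsbreen_near"]] +
                    a[["fjord"]],
                  fjord = a[["fjord"]])
  if (denom <= 0) stop("zero total area")
  c(kronebreen_near = 100 * a[["kronebreen_near"]] / denom,
    kongsbreen_near = 100 * a[["kongsbreen_near"]] / denom)
}

#' Dive density grid
#'
#' Counts points in half-open square bins `[x, x + bin) x [y, y + bin)`.
#' The grid origin defaults to the floor of the point cloud's bounding box in
#' bin units.
#'
#' @param points two-column matrix (x, y), projected metres
#' @param bin_size bin edge length (m), default 100
#' @param origin optional (x, y) of the lower-left grid corner
#' @return object of class `density_grid`: list with `origin`, `bin_size`,
#'   `counts` (integer matrix, rows = x bins, columns = y bins), `xbreaks`,
#'   `ybreaks`
#' @export
density_grid <- function(points, bin_size = 100, origin = NULL) {
  pts <- rbind(points)
  if (is.null(origin)) {
    origin <- c(floor(min(pts[, 1]) / bin_size) * bin_size,
                floor(min(pts[, 2]) / bin_size) * bin_size)
  }
  ix <- floor((pts[, 1] - origin[1]) / bin_size)
  iy <- floor((pts[, 2] - origin[2]) / bin_size)
  if (any(ix < 0) || any(iy < 0)) stop("points fall below the grid origin")
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  counts <- matrix(0L, nx, ny)
  tab <- table(ix = factor(ix, levels = 0:(nx - 1)),
               iy = factor(iy, levels = 0:(ny - 1)))
  counts[] <- as.integer(tab)
  structure(list(origin = origin, bin_size = bin_size, counts = counts,
                 xbreaks = origin[1] + bin_size * 0:nx,
                 ybreaks = origin[2] + bin_size * 0:ny),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %d x %d bins of %g m, %d points\n",
              nrow(x$counts), ncol(x$counts), x$bin_size, sum(x$counts)))
  invisible(x)
}

#' Write a density grid as a CSV matrix with a georeferencing sidecar
#'
#' @param grid a [density_grid()]
#' @param stem path stem; writes `<stem>.csv` (counts, rows = y bins from the
#'   north) and `<stem>_georef.json`
#' @return the two paths, invisibly
#' @export
write_density_grid <- function(grid, stem) {
  csv <- paste0(stem, ".csv")
  side <- paste0(stem, "_georef.json")
  # rows top-down so the matrix reads like a map
  m <- t(grid$counts)[rev(seq_len(ncol(grid$counts))), , drop = FALSE]
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(origin_x = grid$origin[1],
                            origin_y = grid$origin[2],
                            bin_size = grid$bin_size,
                            nx = nrow(grid$counts), ny = ncol(grid$counts),
                            layout = "rows are y bins from north to south"),
                       side, auto_unbox = TRUE, digits = 10)
  invisible(c(grid = csv, georef = side))
}
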