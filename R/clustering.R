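# Monte-Carlo DBSCAN parameter sweep over moving time windows: the
# "percentage of sensitivity tests identifying plume clustering" statistic.

#' DBSCAN clustering of projected points
#'
#' Standard DBSCAN semantics: a point is a core point iff at least `minpts`
#' points (itself included) lie within distance `eps`; clusters are maximal
#' density-connected sets; border points join the first core cluster reaching
#' them in input order (pinned for reproducibility). Noise is labelled 0.
#'
#' @param points two-column matrix (x, y) in metres
#' @param eps neighbourhood radius (m), > 0
#' @param minpts core-point threshold, >= 2
#' @return integer vector of cluster labels (0 = noise)
#' @export
dbscan <- function(points, eps, minpts) {
  stopifnot(eps > 0, minpts >= 2)
  pts <- rbind(points)
  storage.mode(pts) <- "double"
  .dbscan_labels_cpp(pts, eps, as.integer(minpts))
}

#' Sweep configuration
#'
#' @param eps_range range (m) for the uniform eps draw
#' @param minpts_range inclusive integer range for the uniform minPts draw
#' @param n_draws number of random parameter combinations
#' @param window_length moving-window length in days
#' @param window_step window step in days
#' @param seed RNG seed for the parameter draws
#' @param plume_rule how a cluster is attributed to the plume:
#'   `"centroid"` (centroid within the terminus buffer) or `"membership"`
#'   (at least `member_frac` of members within the buffer)
#' @param member_frac membership fraction for the membership rule
#' @param redraw_per_window redraw the parameter set for every window instead
#'   of reusing one fixed set (default FALSE: a fixed set keeps the series
#'   comparable across time)
#' @return named list of class `sweep_config`
#' @export
sweep_config <- function(eps_range = c(25, 200), minpts_range = c(4, 10),
                         n_draws = 1000, window_length = 5, window_step = 1,
                         seed = 1L, plume_rule = c("centroid", "membership"),
                         member_frac = 0.5, redraw_per_window = FALSE) {
  plume_rule <- match.arg(plume_rule)
  stopifnot(length(eps_range) == 2, all(eps_range > 0),
            eps_range[1] <= eps_range[2],
            length(minpts_range) == 2, minpts_range[1] >= 2,
            minpts_range[1] <= minpts_range[2],
            n_draws >= 1, window_length >= 1, window_step >= 1)
  structure(list(eps_range = eps_range, minpts_range = minpts_range,
                 n_draws = as.integer(n_draws),
                 window_length = as.integer(window_length),
                 window_step = as.integer(window_step),
                 seed = seed, plume_rule = plume_rule,
                 member_frac = member_frac,
                 redraw_per_window = redraw_per_window),
            class = "sweep_config")
}

#' Draw random (eps, minPts) parameter combinations
#'
#' eps is continuous-uniform on `eps_range`; minPts is discrete-uniform on
#' the integers of `minpts_range`.
#'
#' @param config a [sweep_config()]
#' @param seed optional seed overriding `config$seed`
#' @return data.frame with `eps` and `minpts`, `n_draws` rows
#' @export
draw_parameters <- function(config, seed = config$seed) {
  with_seed(seed, {
    data.frame(
      eps = runif(config$n_draws, config$eps_range[1], config$eps_range[2]),
      minpts = sample(seq(config$minpts_range[1], config$minpts_range[2]),
                      config$n_draws, replace = TRUE)
    )
  })
}

# terminus polylines as a segment matrix (x1, y1, x2, y2) for the C++ side
.terminus_segments <- function(geometry) {
  seg <- function(line) {
    n <- nrow(line)
    cbind(line[-n, 1], line[-n, 2], line[-1, 1], line[-1, 2])
  }
  rbind(seg(geometry$kronebreen), seg(geometry$kongsbreen))
}

#' Identify plume clusters among DBSCAN labels
#'
#' A cluster is attributed to the plume when its centroid lies within the
#' near-terminus buffer of either front (default), or — under the membership
#' rule — when at least `member_frac` of its members do.
#'
#' @param labels integer cluster labels from [dbscan()]
#' @param points the clustered points (two-column matrix, metres)
#' @param geometry a [terminus_geometry()]
#' @param rule `"centroid"` or `"membership"`
#' @param member_frac membership fraction for the membership rule
#' @return list with `plume_found` (logical) and `clusters` (data.frame
#'   `cluster`, `n`, `centroid_x`, `centroid_y`, `terminus_distance`,
#'   `is_plume`)
#' @export
find_plume_clusters <- function(labels, points, geometry,
                                rule = c("centroid", "membership"),
                                member_frac = 0.5) {
  rule <- match.arg(rule)
  pts <- rbind(points)
  k <- if (length(labels)) max(labels) else 0L
  if (k == 0) {
    return(list(plume_found = FALSE,
                clusters = data.frame(cluster = integer(), n = integer(),
                                      centroid_x = numeric(),
                                      centroid_y = numeric(),
                                      terminus_distance = numeric(),
                                      is_plume = logical())))
  }
  segs <- .terminus_segments(geometry)
  dterm <- pmin(dist_to_polyline(pts, geometry$kronebreen),
                dist_to_polyline(pts, geometry$kongsbreen))
  rows <- lapply(seq_len(k), function(c) {
    m <- labels == c
    cx <- mean(pts[m, 1]); cy <- mean(pts[m, 2])
    cd <- dist_to_polyline(c(cx, cy), geometry$kronebreen)
    cd <- min(cd, dist_to_polyline(c(cx, cy), geometry$kongsbreen))
    is_plume <- if (rule == "centroid") {
      cd <= geometry$buffer_distance
    } else {
      mean(dterm[m] <= geometry$buffer_distance) >= member_frac
    }
    data.frame(cluster = c, n = sum(m), centroid_x = cx, centroid_y = cy,
               terminus_distance = cd, is_plume = is_plume)
  })
  clusters <- do.call(rbind, rows)
  list(plume_found = any(clusters$is_plume), clusters = clusters)
}

#' Moving-window Monte-Carlo DBSCAN sweep
#'
#' For each window of `window_length` days (stepped by `window_step`, labelled
#' by its centre day), DBSCAN is run once per random (eps, minPts) draw on the
#' dive locations inside the window. The headline statistic is the percentage
#' of draws in which a plume cluster is found; the percentage of profiles in
#' any cluster (averaged over draws) is reported alongside. Windows with no
#' dives score 0%.
#'
#' @param dates per-dive dates (`Date` vector, same length as `points` rows)
#' @param points two-column matrix of projected dive locations (m)
#' @param geometry a [terminus_geometry()]
#' @param config a [sweep_config()]
#' @param date_range optional `c(start, end)` `Date` pair for the series span
#'   (defaults to the data span)
#' @return object of class `cluster_density_series`: list with `series`
#'   (data.frame `date`, `pct_tests`, `pct_profiles_in_clusters`,
#'   `n_profiles`), `draws` (the parameter draws used for the first window),
#'   `per_draw` (list of per-window data.frames `eps`, `minpts`,
#'   `n_clusters`, `plume_found`), and `config`
#' @export
windowed_sweep <- function(dates, points, geometry, config = sweep_config(),
                           date_range = NULL) {
  stopifnot(inherits(dates, "Date"))
  pts <- rbind(points)
  stopifnot(nrow(pts) == length(dates))
  if (is.null(date_range)) date_range <- range(dates)
  days <- seq(date_range[1], date_range[2], by = "day")
  half <- (config$window_length - 1) / 2
  centres <- days[seq(1, length(days), by = config$window_step)]
  segs <- .terminus_segments(geometry)
  rule <- if (config$plume_rule == "centroid") 0L else 1L
  dterm_all <- pmin(dist_to_polyline(pts, geometry$kronebreen),
                    dist_to_polyline(pts, geometry$kongsbreen))
  draws <- draw_parameters(config)
  out <- vector("list", length(centres))
  per_draw <- vector("list", length(centres))
  for (w in seq_along(centres)) {
    if (config$redraw_per_window) {
      draws_w <- draw_parameters(config, seed = derive_seed(config$seed, w))
    } else {
      draws_w <- draws
    }
    lo <- centres[w] - ceiling(half)
    hi <- centres[w] + floor(half)
    m <- dates >= lo & dates <= hi
    n <- sum(m)
    if (n == 0) {
      out[[w]] <- data.frame(date = centres[w], pct_tests = 0,
                             pct_profiles_in_clusters = 0, n_profiles = 0L)
      per_draw[[w]] <- data.frame(eps = draws_w$eps, minpts = draws_w$minpts,
                                  n_clusters = 0L, plume_found = FALSE)
      next
    }
    wpts <- pts[m, , drop = FALSE]
    storage.mode(wpts) <- "double"
    res <- .dbscan_sweep_cpp(wpts, draws_w$eps, as.integer(draws_w$minpts),
                             segs, geometry$buffer_distance, rule,
                             config$member_frac, dterm_all[m])
    out[[w]] <- data.frame(
      date = centres[w],
      pct_tests = 100 * mean(res$plume_found),
      pct_profiles_in_clusters = 100 * mean(res$frac_in_clusters),
      n_profiles = n
    )
    per_draw[[w]] <- data.frame(eps = draws_w$eps, minpts = draws_w$minpts,
                                n_clusters = res$n_clusters,
                                plume_found = res$plume_found)
  }
  structure(list(series = do.call(rbind, out), draws = draws,
                 per_draw = per_draw, config = config),
            class = "cluster_density_series")
}

#' @export
print.cluster_density_series <- function(x, ...) {
  s <- x$series
  cat(sprintf("Cluster-density series: %d windows (%s to %s), %d draws/window\n",
              nrow(s), format(min(s$date)), format(max(s$date)),
              x$config$n_draws))
  cat(sprintf("  pct_tests: max %.1f%% on %s\n",
              max(s$pct_tests), format(s$date[which.max(s$pct_tests)])))
  invisible(x)
}

#' Write a cluster-density series to CSV
#'
#' @param x a `cluster_density_series`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_cluster_series_csv <- function(x, path) {
  write.csv(x$series, path, row.names = FALSE)
  invisible(path)
}
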