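# Temporal coupling of the runoff and cluster-density series: peak detection
# with the standard prominence definition, greedy nearest-in-time pairing,
# and the daily in-plume timeline.

#' Detect peaks in a daily series
#'
#' Local maxima with prominence at least `min_prominence` and mutual
#' separation at least `min_separation` days. Prominence follows the standard
#' definition: the drop from the peak to the higher of the two lowest points
#' separating it from higher terrain (or from the series ends). Plateaus are
#' reduced to their centre day. When peaks compete within the separation
#' window the higher one wins.
#'
#' @param dates `Date` vector (daily, contiguous)
#' @param values numeric series values
#' @param min_prominence minimum prominence (same units as `values`)
#' @param min_separation minimum distance between kept peaks (days)
#' @param refine `"argmax"` reports the day of the local maximum;
#'   `"centroid"` refines the date to the centre of mass of the series above
#'   half prominence around the maximum, which localises noisy, flat-topped
#'   peaks far more stably
#' @return data.frame with `date`, `height`, `prominence`
#' @export
detect_peaks <- function(dates, values, min_prominence = 0,
                         min_separation = 1,
                         refine = c("argmax", "centroid")) {
  refine <- match.arg(refine)
  stopifnot(length(dates) == length(values), length(values) >= 1)
  if (length(unique(as.numeric(diff(dates)))) > 1) {
    stop("series must be daily and contiguous")
  }
  n <- length(values)
  # candidate local maxima; plateaus contribute their centre index
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && values[j + 1] == values[i]) j <- j + 1
    left_ok <- i == 1 || values[i - 1] < values[i]
    right_ok <- j == n || values[j + 1] < values[i]
    if (left_ok && right_ok && !(i == 1 && j == n)) {
      cand <- c(cand, as.integer(floor((i + j) / 2)))
    }
    i <- j + 1
  }
  if (!length(cand)) {
    return(data.frame(date = as.Date(character()), height = numeric(),
                      prominence = numeric()))
  }
  prominence <- vapply(cand, function(p) {
    h <- values[p]
    lmin <- h
    k <- p
    while (k > 1) {
      k <- k - 1
      if (values[k] > h) break
      if (values[k] < lmin) lmin <- values[k]
    }
    if (values[k] <= h) lmin <- min(lmin, values[seq_len(k)])
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1
      if (values[k] > h) break
      if (values[k] < rmin) rmin <- values[k]
    }
    if (values[k] <= h) rmin <- min(rmin, values[k:n])
    h - max(lmin, rmin)
  }, 0)
  keep <- prominence >= min_prominence & prominence > 0
  cand <- cand[keep]; prominence <- prominence[keep]
  # enforce separation greedily from the highest peak down
  ord <- order(values[cand], decreasing = TRUE)
  sel <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - cand[sel]) >= min_separation)) sel <- c(sel, k)
  }
  sel <- sel[order(cand[sel])]
  peak_dates <- dates[cand[sel]]
  if (refine == "centroid") {
    peak_dates <- as.Date(vapply(seq_along(sel), function(k) {
      p <- cand[sel[k]]
      cut <- values[p] - prominence[sel[k]] / 2
      lo <- p; while (lo > 1 && values[lo - 1] >= cut) lo <- lo - 1
      hi <- p; while (hi < n && values[hi + 1] >= cut) hi <- hi + 1
      w <- values[lo:hi] - cut
      round(sum(as.numeric(dates[lo:hi]) * w) / sum(w))
    }, 0), origin = "1970-01-01")
  }
  data.frame(date = peak_dates, height = values[cand[sel]],
             prominence = prominence[sel])
}

#' Pair runoff and clustering peaks
#'
#' Greedy nearest-in-time matching within `max_lag` days: candidate pairs are
#' sorted by absolute lag and accepted while both peaks are unused, which is
#' symmetric in the two series. Unmatched peaks are reported on both sides.
#'
#' @param runoff_peaks,clustering_peaks data.frames from [detect_peaks()]
#' @param max_lag largest acceptable |lag| in days (default 3)
#' @return list with `pairs` (data.frame `runoff_date`, `clustering_date`,
#'   `lag_days` = clustering minus runoff), `unmatched_runoff`,
#'   `unmatched_clustering` (`Date` vectors)
#' @export
pair_peaks <- function(runoff_peaks, clustering_peaks, max_lag = 3) {
  nr <- nrow(runoff_peaks); nc <- nrow(clustering_peaks)
  pairs <- data.frame(runoff_date = as.Date(character()),
                      clustering_date = as.Date(character()),
                      lag_days = numeric())
  if (nr && nc) {
    cand <- expand.grid(i = seq_len(nr), j = seq_len(nc))
    cand$lag <- as.numeric(clustering_peaks$date[cand$j] -
                             runoff_peaks$date[cand$i])
    cand <- cand[abs(cand$lag) <= max_lag, , drop = FALSE]
    cand <- cand[order(abs(cand$lag), cand$i), , drop = FALSE]
    used_i <- logical(nr); used_j <- logical(nc)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        runoff_date = runoff_peaks$date[i],
        clustering_date = clustering_peaks$date[j],
        lag_days = cand$lag[k]))
    }
  } else {
    used_i <- logical(nr); used_j <- logical(nc)
  }
  list(pairs = pairs,
       unmatched_runoff = runoff_peaks$date[!used_i],
       unmatched_clustering = clustering_peaks$date[!used_j])
}

#' Daily timeline of in-plume profiles
#'
#' Aggregates in-plume profiles by day: count and mean subglacial discharge
#' fraction (per profile the mean over its valid spiked samples, then the
#' daily mean over profiles). Returns an empty table when no profile is
#' in-plume.
#'
#' @param dives data.frame with `profile_id` and `dive_time`
#' @param decomposed per-sample data.frame with `profile_id`, `f_sg`,
#'   `valid` and logical `spike`
#' @return data.frame with `date`, `n_in_plume`, `mean_fsg`
#' @export
in_plume_timeline <- function(dives, decomposed) {
  use <- decomposed$valid & decomposed$spike
  if (!any(use)) {
    return(data.frame(date = as.Date(character()), n_in_plume = integer(),
                      mean_fsg = numeric()))
  }
  per_profile <- tapply(decomposed$f_sg[use], decomposed$profile_id[use], mean)
  date <- as.Date(dives$dive_time[match(names(per_profile),
                                        dives$profile_id)])
  agg <- aggregate(list(mean_fsg = as.numeric(per_profile)),
                   by = list(date = date), FUN = mean)
  cnt <- aggregate(list(n_in_plume = names(per_profile)),
                   by = list(date = date), FUN = length)
  out <- merge(cnt, agg, by = "date")
  out[order(out$date), c("date", "n_in_plume", "mean_fsg")]
}

#' Build the machine-readable pipeline report
#'
#' Collects the stage outputs of a [plume_analysis()] into one JSON-ready
#' list: region percentages, uniform expectations, maximum f_sg, the
#' cluster-density series, peak pairings, the in-plume timeline, a config
#' echo, the seed and the package version.
#'
#' @param fit a [plume_analysis()] result
#' @return nested list suitable for [write_report()]
#' @export
build_report <- function(fit) {
  stopifnot(inherits(fit, "plume_analysis"))
  for (stage in c("regions", "uniform_expectation", "max_fsg", "clustering",
                  "peaks")) {
    if (is.null(fit[[stage]])) stop("missing upstream output: ", stage)
  }
  s <- fit$clustering$series
  list(
    regions = fit$regions,
    uniform_expectation_pct = as.list(fit$uniform_expectation),
    max_fsg = fit$max_fsg[c("f_sg", "depth", "profile_id", "n")],
    cluster_density = data.frame(date = format(s$date),
                                 pct_tests = s$pct_tests,
                                 pct_profiles_in_clusters =
                                   s$pct_profiles_in_clusters,
                                 n_profiles = s$n_profiles),
    peak_pairing = list(
      pairs = if (nrow(fit$peaks$pairing$pairs)) {
        data.frame(runoff_date = format(fit$peaks$pairing$pairs$runoff_date),
                   clustering_date =
                     format(fit$peaks$pairing$pairs$clustering_date),
                   lag_days = fit$peaks$pairing$pairs$lag_days)
      } else list(),
      unmatched_runoff = format(fit$peaks$pairing$unmatched_runoff),
      unmatched_clustering = format(fit$peaks$pairing$unmatched_clustering)
    ),
    in_plume_timeline = if (nrow(fit$timeline)) {
      data.frame(date = format(fit$timeline$date),
                 n_in_plume = fit$timeline$n_in_plume,
                 mean_fsg = fit$timeline$mean_fsg)
    } else list(),
    n_profiles_kept = nrow(fit$profiles$dives),
    rejections = if (nrow(fit$rejection_log)) {
      as.list(table(fit$rejection_log$reason))
    } else list(),
    config = .jsonable(fit$config),
    seed = fit$config$seed,
    package_version = as.character(utils::packageVersion("sealplume"))
  )
}

# strip classes/functions so a config echo serialises cleanly to JSON
.jsonable <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, "Date") || inherits(x, "POSIXt")) return(format(x))
  if (is.list(x)) {
    out <- lapply(unclass(x), .jsonable)
    return(out[!vapply(out, is.null, TRUE)])
  }
  x
}

#' Write the pipeline report to JSON
#'
#' @param report a [build_report()] list
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       Date = "ISO8601", dataframe = "rows")
  invisible(path)
}
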