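# End-to-end pipeline: QC -> geolocation/regions -> water-mass decomposition
# -> Monte-Carlo DBSCAN sweep -> temporal coupling, wrapped in one classed
# result object.

#' Pipeline configuration
#'
#' @param thresholds QC thresholds, see [qc_thresholds()]
#' @param max_interp_run,flag_cap profile exclusion rules, see
#'   [filter_profiles()]
#' @param cutoff_date ambient-endmember cutoff: only fjord profiles before
#'   this date define the ambient water mass
#' @param reference_pressure grounding-line pressure (dbar) for the runoff
#'   and meltwater endmembers
#' @param depth_band ambient averaging band thickness (m)
#' @param spike_k spike threshold multiplier (salinity anomalies beyond
#'   `spike_k * sigma_s` flag a profile as in-plume)
#' @param sigma_s,sigma_t instrument uncertainties (g/kg, degC)
#' @param epsilon validity tolerance on mixing fractions
#' @param sweep a [sweep_config()]
#' @param min_prominence_frac peak prominence threshold as a fraction of the
#'   series maximum
#' @param min_separation minimum days between detected peaks
#' @param peak_refine peak-date refinement passed to [detect_peaks()]
#' @param peak_series which clustering statistic the peak pairing uses:
#'   `"participation"` (percentage of profiles in clusters — roughly linear
#'   in clustering intensity, so its peaks localise well) or `"tests"`
#'   (percentage of parameter draws identifying a plume cluster — the
#'   headline series, but it saturates near 100% during dense clustering)
#' @param max_lag pairing window (days)
#' @param uniform_denominator `"total"` or `"fjord"`, see
#'   [uniform_expectation()]
#' @param seed seed forwarded to the sweep when it has none
#' @return named list of class `plume_config`
#' @export
plume_config <- function(thresholds = qc_thresholds(),
                         max_interp_run = 3, flag_cap = 0.2,
                         cutoff_date = as.POSIXct("2012-09-20", tz = "UTC"),
                         reference_pressure = 100, depth_band = 20,
                         spike_k = 5, sigma_s = 0.1, sigma_t = 0.02,
                         epsilon = 0.02,
                         sweep = sweep_config(),
                         min_prominence_frac = 0.2, min_separation = 4,
                         peak_refine = "centroid",
                         peak_series = c("participation", "tests"),
                         max_lag = 3,
                         uniform_denominator = c("total", "fjord"),
                         seed = 1L) {
  uniform_denominator <- match.arg(uniform_denominator)
  peak_series <- match.arg(peak_series)
  structure(as.list(environment()), class = "plume_config")
}

#' Run the full plume-detection pipeline
#'
#' Quality-controls and filters the profiles, classifies dive regions,
#' builds endmembers from pre-cutoff fjord profiles and decomposes every
#' sample into ambient / subglacial-runoff / meltwater fractions, detects
#' low-salinity spikes, runs the moving-window Monte-Carlo DBSCAN sweep on
#' the dive locations, and couples the resulting cluster-density series to
#' the runoff series by peak pairing.
#'
#' @param profiles a [profile_set()] (raw; conversion and QC are applied
#'   here)
#' @param geometry a [terminus_geometry()]
#' @param runoff data.frame with `day` (`Date`) and `discharge` (m^3/s)
#' @param config a [plume_config()]
#' @return an object of class `plume_analysis` with components `profiles`
#'   (kept, converted), `rejection_log`, `regions`, `uniform_expectation`,
#'   `endmembers`, `decomposed`, `spikes`, `max_fsg`, `clustering`,
#'   `runoff`, `peaks`, `timeline`, `geometry`, `config`
#' @export
plume_analysis <- function(profiles, geometry, runoff,
                           config = plume_config()) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(geometry, "terminus_geometry"))

  prof <- convert_teos10(profiles)
  prof <- qc_samples(prof, config$thresholds)
  filt <- filter_profiles(prof, max_interp_run = config$max_interp_run,
                          flag_cap = config$flag_cap)
  kept <- filt$kept
  if (!nrow(kept$dives)) stop("no profiles survive filtering")

  d <- kept$dives
  if (is.null(d$x) || is.null(d$y)) {
    xy <- utm_project(d$lon, d$lat, zone = geometry$zone)
    d$x <- xy[, "x"]; d$y <- xy[, "y"]
  }
  d$region <- classify_region(cbind(d$x, d$y), geometry)
  kept <- profile_set(d, kept$samples)

  regions <- region_percentages(d$region)
  uniform <- uniform_expectation(geometry, config$uniform_denominator)

  em <- build_endmembers(kept, config$cutoff_date, geometry,
                         depth_band = config$depth_band,
                         reference_pressure = config$reference_pressure)
  s <- kept$samples
  fr <- decompose_fractions(s$theta, s$sa, em, epsilon = config$epsilon)
  decomposed <- cbind(s[, c("profile_id", "depth", "theta", "sa")], fr)
  amb_fun <- ambient_profile_fun(kept)
  sp <- detect_salinity_spikes(decomposed, amb_fun, k = config$spike_k,
                               sigma_s = config$sigma_s)
  decomposed$spike <- sp$is_spike
  fsg <- max_fsg(decomposed, in_plume = sp$in_plume)

  sweep_cfg <- config$sweep
  if (is.null(sweep_cfg$seed)) sweep_cfg$seed <- config$seed
  clustering <- windowed_sweep(as.Date(d$dive_time), cbind(d$x, d$y),
                               geometry, sweep_cfg,
                               date_range = range(runoff$day))

  rp <- detect_peaks(runoff$day, runoff$discharge,
                     min_prominence = config$min_prominence_frac *
                       max(runoff$discharge),
                     min_separation = config$min_separation,
                     refine = config$peak_refine)
  cs <- clustering$series
  cvals <- if (config$peak_series == "participation") {
    cs$pct_profiles_in_clusters
  } else {
    cs$pct_tests
  }
  cp <- detect_peaks(cs$date, cvals,
                     min_prominence = config$min_prominence_frac * max(cvals),
                     min_separation = config$min_separation,
                     refine = config$peak_refine)
  pairing <- pair_peaks(rp, cp, max_lag = config$max_lag)
  timeline <- in_plume_timeline(d, decomposed)

  structure(list(profiles = kept, rejection_log = filt$log,
                 regions = regions, uniform_expectation = uniform,
                 endmembers = em, decomposed = decomposed,
                 spikes = sp, max_fsg = fsg,
                 clustering = clustering, runoff = runoff,
                 peaks = list(runoff_peaks = rp, clustering_peaks = cp,
                              pairing = pairing),
                 timeline = timeline, geometry = geometry, config = config),
            class = "plume_analysis")
}

#' @export
print.plume_analysis <- function(x, ...) {
  cat("Seal-borne CTD plume analysis\n")
  cat(sprintf("  profiles kept: %d (%d rejected)\n",
              nrow(x$profiles$dives), nrow(x$rejection_log)))
  r <- x$regions
  cat("  regions: ",
      paste(sprintf("%s %d%%", r$region, r$percent_int), collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$max_fsg$f_sg)) {
    cat(sprintf("  max f_sg: %.1f%% at %.0f m (profile %s)\n",
                100 * x$max_fsg$f_sg, x$max_fsg$depth,
                x$max_fsg$profile_id))
  } else {
    cat("  max f_sg: no valid in-plume samples\n")
  }
  np <- nrow(x$peaks$pairing$pairs)
  cat(sprintf("  peak pairing: %d runoff peak(s) matched to clustering peaks\n",
              np))
  invisible(x)
}

#' @export
summary.plume_analysis <- function(object, ...) {
  x <- object
  print(x)
  cat("\nUniform-diving expectation (%):\n")
  print(round(x$uniform_expectation, 2))
  cat("\nEndmembers:\n")
  print(x$endmembers)
  cat("\nRunoff peaks:\n"); print(x$peaks$runoff_peaks)
  cat("\nClustering peaks:\n"); print(x$peaks$clustering_peaks)
  cat("\nPairs (lag = clustering - runoff, days):\n")
  print(x$peaks$pairing$pairs)
  if (nrow(x$timeline)) {
    cat("\nIn-plume profiles by day:\n"); print(x$timeline)
  }
  invisible(x)
}

#' Plot a plume analysis
#'
#' Two aligned panels: the runoff series with its detected peaks, and the
#' percentage of sensitivity tests identifying plume clustering with in-plume
#' profile days overlaid.
#'
#' @param x a [plume_analysis()] result
#' @param ... ignored
#' @return `x`, invisibly
#' @export
plot.plume_analysis <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(op), add = TRUE)
  plot(x$runoff$day, x$runoff$discharge, type = "l",
       xlab = "", ylab = "runoff [m3/s]")
  points(x$peaks$runoff_peaks$date, x$peaks$runoff_peaks$height,
         pch = 17, col = "red")
  s <- x$clustering$series
  plot(s$date, s$pct_tests, type = "l",
       xlab = "", ylab = "% tests with plume cluster", ylim = c(0, 100))
  points(x$peaks$clustering_peaks$date, x$peaks$clustering_peaks$height,
         pch = 17, col = "red")
  if (nrow(x$timeline)) {
    points(x$timeline$date, 100 * x$timeline$mean_fsg, pch = 19,
           col = "darkred")
  }
  invisible(x)
}

#' Write the per-sample decomposition table as CSV with a JSON provenance
#' sidecar
#'
#' @param fit a [plume_analysis()] result
#' @param stem path stem; writes `<stem>.csv` and `<stem>_endmembers.json`
#' @return the two paths, invisibly
#' @export
write_decomposition_csv <- function(fit, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, "_endmembers.json")
  write.csv(fit$decomposed, csv, row.names = FALSE)
  em <- fit$endmembers
  jsonlite::write_json(list(ambient = as.list(em$ambient),
                            runoff = as.list(em$runoff),
                            meltwater = as.list(em$meltwater),
                            constants = as.list(em$constants),
                            reference_pressure = em$reference_pressure),
                       js, auto_unbox = TRUE, digits = 10)
  invisible(c(table = csv, endmembers = js))
}
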