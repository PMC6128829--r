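# Dive-profile container: a dive table (one row per transmitted dive) plus a
# sample table (one row per depth sample), linked by profile_id. Plain
# data.frames inside a light S3 wrapper.

#' Dive profile set
#'
#' @param dives data.frame with one row per dive: `profile_id`, `seal_id`,
#'   `dive_time` (POSIXct, UTC), `lon`, `lat` (degrees), `x`, `y` (projected
#'   metres, optional), `location_source` ("gps" or "interpolated"),
#'   `interp_run_length` (count of consecutive interpolated locations
#'   including this one; 0 for GPS locations)
#' @param samples data.frame with one row per sample: `profile_id`,
#'   `pressure` (dbar), `temp_insitu` (degC), `psal` (practical salinity),
#'   `interp_t`, `interp_s` (logical: value interpolated within the profile).
#'   Processed sets additionally carry `theta`, `sa`, `depth`, QC flag
#'   columns and `flagged`.
#' @return an object of class `profile_set`
#' @export
profile_set <- function(dives, samples) {
  need_d <- c("profile_id", "seal_id", "dive_time", "lon", "lat",
              "location_source", "interp_run_length")
  need_s <- c("profile_id", "pressure", "temp_insitu", "psal")
  miss <- setdiff(need_d, names(dives))
  if (length(miss)) stop("dives is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("samples is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(dives$profile_id)) stop("duplicated profile_id in dives")
  if (!all(samples$profile_id %in% dives$profile_id)) {
    stop("samples reference unknown profile_id values")
  }
  if (is.null(samples$interp_t)) samples$interp_t <- FALSE
  if (is.null(samples$interp_s)) samples$interp_s <- FALSE
  structure(list(dives = dives, samples = samples), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("Profile set: %d dives, %d samples, %d seals\n",
              nrow(x$dives), nrow(x$samples),
              length(unique(x$dives$seal_id))))
  if (nrow(x$dives)) {
    cat(sprintf("  time span: %s to %s\n",
                format(min(x$dives$dive_time), "%Y-%m-%d"),
                format(max(x$dives$dive_time), "%Y-%m-%d")))
    cat(sprintf("  locations: %d gps, %d interpolated\n",
                sum(x$dives$location_source == "gps"),
                sum(x$dives$location_source == "interpolated")))
  }
  if (!is.null(x$samples$theta)) cat("  TEOS-10 converted\n")
  if (!is.null(x$dives$kept)) {
    cat(sprintf("  kept after filtering: %d of %d\n",
                sum(x$dives$kept), nrow(x$dives)))
  }
  invisible(x)
}

# subset a profile_set to the dives with the given profile ids
subset_profiles <- function(profiles, ids) {
  profile_set(profiles$dives[profiles$dives$profile_id %in% ids, , drop = FALSE],
              profiles$samples[profiles$samples$profile_id %in% ids, , drop = FALSE])
}

#' Write a profile set to CSV
#'
#' Two files: `<stem>_dives.csv` and `<stem>_samples.csv`.
#'
#' @param profiles a [profile_set()]
#' @param stem path stem (directory + file prefix)
#' @return the two paths, invisibly
#' @export
write_profiles_csv <- function(profiles, stem) {
  dp <- paste0(stem, "_dives.csv")
  sp <- paste0(stem, "_samples.csv")
  d <- profiles$dives
  d$dive_time <- format(d$dive_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(d, dp, row.names = FALSE)
  write.csv(profiles$samples, sp, row.names = FALSE)
  invisible(c(dives = dp, samples = sp))
}

#' Read a profile set from CSV
#'
#' @param stem path stem used by [write_profiles_csv()]
#' @return a [profile_set()]
#' @export
read_profiles_csv <- function(stem) {
  d <- read.csv(paste0(stem, "_dives.csv"))
  s <- read.csv(paste0(stem, "_samples.csv"))
  d$dive_time <- as.POSIXct(d$dive_time, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  for (col in intersect(c("interp_t", "interp_s", "flagged"), names(s))) {
    s[[col]] <- as.logical(s[[col]])
  }
  profile_set(d, s)
}
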