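# Quality control of dive profiles: TEOS-10 conversion, Argo-style real-time
# sample tests (gross range, spike, gradient, density inversion) and
# profile-level exclusion rules. Flags never alter sample values.

#' Default QC thresholds
#'
#' Gross ranges are set for inner-fjord water (which violates open-ocean
#' climatological ranges); spike and gradient thresholds are the Argo
#' real-time shallow-water values.
#'
#' @param theta_range gross range for conservative temperature (degC)
#' @param sa_range gross range for absolute salinity (g/kg)
#' @param spike_theta,spike_sa spike-test thresholds (degC, g/kg)
#' @param gradient_theta,gradient_sa gradient-test thresholds (degC, g/kg)
#' @param density_tol allowed potential-density decrease with depth (kg/m^3)
#' @return named list of thresholds
#' @export
qc_thresholds <- function(theta_range = c(-2.5, 15), sa_range = c(0, 36),
                          spike_theta = 6, spike_sa = 0.9,
                          gradient_theta = 9, gradient_sa = 1.5,
                          density_tol = 0.03) {
  list(theta_range = theta_range, sa_range = sa_range,
       spike_theta = spike_theta, spike_sa = spike_sa,
       gradient_theta = gradient_theta, gradient_sa = gradient_sa,
       density_tol = density_tol)
}

#' Convert profiles to TEOS-10 variables
#'
#' Adds per-sample absolute salinity `sa` (from practical salinity),
#' conservative temperature `theta` (from in-situ temperature and pressure)
#' and `depth` (from pressure and latitude). Requires a location per dive
#' (latitude enters the depth conversion).
#'
#' @param profiles a [profile_set()]
#' @return the profile set with `theta`, `sa`, `depth` sample columns
#' @export
convert_teos10 <- function(profiles) {
  dives <- profiles$dives
  missing_loc <- is.na(dives$lon) | is.na(dives$lat)
  if (any(missing_loc)) {
    stop("missing location for dive(s): ",
         paste(dives$profile_id[missing_loc], collapse = ", "))
  }
  s <- profiles$samples
  lat <- dives$lat[match(s$profile_id, dives$profile_id)]
  s$sa <- sa_from_sp(s$psal)
  s$theta <- ct_from_insitu(s$psal, s$temp_insitu, s$pressure)
  s$depth <- depth_from_pressure(s$pressure, lat)
  profile_set(dives, s)
}

# apply a centred 3-point test statistic within each profile; returns a
# logical flag for the middle sample of each interior triple
.triple_flag <- function(pid, v, stat_fun, threshold) {
  n <- length(v)
  flag <- rep(FALSE, n)
  if (n < 3) return(flag)
  i <- 2:(n - 1)
  ok <- pid[i] == pid[i - 1] & pid[i] == pid[i + 1]  # same profile
  tv <- stat_fun(v[i - 1], v[i], v[i + 1])
  flag[i] <- ok & tv > threshold
  flag
}

#' Argo-style sample QC
#'
#' Applies the gross-range, spike, gradient and density-inversion tests to a
#' converted profile set. Failing samples are flagged, never deleted. The
#' `flagged` summary column combines gross-range, spike and gradient flags;
#' density-inversion flags are reported separately because statically
#' unstable water is an expected, genuine signal inside a buoyant plume.
#'
#' @param profiles a converted [profile_set()] (see [convert_teos10()])
#' @param thresholds a list from [qc_thresholds()]
#' @return the profile set with logical sample columns `qc_gross_range`,
#'   `qc_spike`, `qc_gradient`, `qc_density_inversion` and `flagged`
#' @export
qc_samples <- function(profiles, thresholds = qc_thresholds()) {
  s <- profiles$samples
  if (is.null(s$theta)) stop("run convert_teos10() before qc_samples()")
  ord <- order(s$profile_id, s$pressure)
  s <- s[ord, , drop = FALSE]
  th <- thresholds
  s$qc_gross_range <- s$theta < th$theta_range[1] | s$theta > th$theta_range[2] |
    s$sa < th$sa_range[1] | s$sa > th$sa_range[2]
  spike_stat <- function(a, b, c) abs(b - (a + c) / 2) - abs(c - a) / 2
  grad_stat <- function(a, b, c) abs(b - (a + c) / 2)
  pid <- s$profile_id
  s$qc_spike <- .triple_flag(pid, s$theta, spike_stat, th$spike_theta) |
    .triple_flag(pid, s$sa, spike_stat, th$spike_sa)
  s$qc_gradient <- .triple_flag(pid, s$theta, grad_stat, th$gradient_theta) |
    .triple_flag(pid, s$sa, grad_stat, th$gradient_sa)
  # density inversion: potential density must not decrease with depth by more
  # than the tolerance; the deeper sample of an inverted pair is flagged
  sg <- sigma0(sp_from_sa(s$sa), s$theta)
  n <- nrow(s)
  inv <- rep(FALSE, n)
  if (n >= 2) {
    i <- 2:n
    same <- pid[i] == pid[i - 1]
    inv[i] <- same & (sg[i] < sg[i - 1] - th$density_tol)
  }
  s$qc_density_inversion <- inv
  s$flagged <- s$qc_gross_range | s$qc_spike | s$qc_gradient
  profile_set(profiles$dives, s)
}

#' Apply the profile-level exclusion rules
#'
#' Drops profiles whose location comes from a run of more than
#' `max_interp_run` consecutive interpolated locations, profiles containing
#' any interpolated temperature or salinity value, and profiles whose flagged
#' sample fraction exceeds `flag_cap`. Each rejection is logged with exactly
#' one (primary) reason; the rules are checked in the order above. Filtering
#' is idempotent.
#'
#' @param profiles a QC'd [profile_set()]
#' @param max_interp_run largest acceptable run of consecutive interpolated
#'   locations (default 3: a run of 4 or more rejects)
#' @param flag_cap largest acceptable fraction of QC-flagged samples per
#'   profile (default 0.2)
#' @return list with `kept` (a [profile_set()] of the retained profiles) and
#'   `log` (data.frame `profile_id`, `seal_id`, `dive_time`, `reason`)
#' @export
filter_profiles <- function(profiles, max_interp_run = 3, flag_cap = 0.2) {
  d <- profiles$dives
  s <- profiles$samples
  reason <- rep(NA_character_, nrow(d))

  run_bad <- d$interp_run_length > max_interp_run
  reason[run_bad] <- "location-interpolation run"

  interp_vals <- s$interp_t | s$interp_s
  bad_ids <- unique(s$profile_id[interp_vals])
  val_bad <- d$profile_id %in% bad_ids & is.na(reason)
  reason[val_bad] <- "interpolated values"

  if (!is.null(s$flagged)) {
    frac <- tapply(s$flagged, s$profile_id, mean)
    f <- as.numeric(frac)[match(d$profile_id, names(frac))]
    f[is.na(f)] <- 0
    cap_bad <- f > flag_cap & is.na(reason)
    reason[cap_bad] <- "qc-flag fraction"
  }

  keep <- is.na(reason)
  log <- data.frame(profile_id = d$profile_id[!keep],
                    seal_id = d$seal_id[!keep],
                    dive_time = d$dive_time[!keep],
                    reason = reason[!keep])
  list(kept = subset_profiles(profiles, d$profile_id[keep]), log = log)
}
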