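# Three-endmember water-mass decomposition in Theta-S_A space.
#
# Every sample is written as a mixture of
#   * ambient fjord water        (Theta_a, S_a)
#   * subglacial runoff          (Theta_r, 0)  - freshwater at the pressure
#     melting point at the grounding line
#   * submarine meltwater        (Theta_m, 0)  - the Gade effective endmember,
#     whose temperature is depressed by the latent heat of melting and the
#     heat needed to warm the ice to the freezing point
# under conservation of mass, heat and salt. With three endmembers and three
# conservation equations the system is square and solved exactly; fractions
# are reported unclamped with a validity flag.

#' Gade effective meltwater temperature
#'
#' `Theta_m = Theta_f - L/c_p - (c_i/c_p) * (Theta_f - T_i)`: the virtual
#' temperature of the meltwater endmember after paying the latent heat of
#' melting and warming the ice from its core temperature to the freezing
#' point.
#'
#' @param theta_f freezing temperature at the grounding line (degC)
#' @param L latent heat of fusion (J/kg)
#' @param cp specific heat capacity of seawater (J/kg/K)
#' @param ci specific heat capacity of ice (J/kg/K)
#' @param Ti ice core temperature (degC, <= 0)
#' @return effective meltwater endmember temperature (degC)
#' @export
gade_effective_temperature <- function(theta_f, L = 3.35e5, cp = 3.98e3,
                                       ci = 2.1e3, Ti = -10) {
  if (cp <= 0) stop("cp must be positive")
  theta_f - L / cp - (ci / cp) * (theta_f - Ti)
}

#' Endmember set for the three-way decomposition
#'
#' Builds the ambient / runoff / meltwater endmembers from an ambient
#' (Theta, S_A) pair and thermodynamic constants. The runoff endmember is
#' freshwater at the pressure melting point at `reference_pressure` (the
#' grounding-line pressure); the meltwater endmember uses the Gade
#' construction at the freezing point of the *ambient* salinity at that
#' pressure.
#'
#' @param ambient numeric vector `c(theta, sa)`: ambient conservative
#'   temperature (degC) and absolute salinity (g/kg)
#' @param reference_pressure grounding-line pressure (dbar)
#' @param L,cp,ci,Ti thermodynamic constants, see
#'   [gade_effective_temperature()]
#' @return an object of class `endmember_set` with elements `ambient`,
#'   `runoff`, `meltwater` (each `c(theta, sa)`), `constants` and
#'   `reference_pressure`
#' @export
endmember_set <- function(ambient, reference_pressure = 100,
                          L = 3.35e5, cp = 3.98e3, ci = 2.1e3, Ti = -10) {
  ambient <- unname(ambient)
  stopifnot(length(ambient) == 2, ambient[2] > 0,
            L > 0, cp > 0, ci >= 0, Ti <= 0, reference_pressure >= 0)
  theta_r <- freezing_temperature(0, reference_pressure)
  theta_f_amb <- freezing_temperature(ambient[2], reference_pressure)
  theta_m <- gade_effective_temperature(theta_f_amb, L = L, cp = cp,
                                        ci = ci, Ti = Ti)
  structure(list(
    ambient = c(theta = ambient[1], sa = ambient[2]),
    runoff = c(theta = theta_r, sa = 0),
    meltwater = c(theta = theta_m, sa = 0),
    constants = c(L = L, cp = cp, ci = ci, Ti = Ti),
    reference_pressure = reference_pressure
  ), class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat("Endmember set (reference pressure", x$reference_pressure, "dbar)\n")
  for (nm in c("ambient", "runoff", "meltwater")) {
    cat(sprintf("  %-9s Theta = %8.3f degC, S_A = %6.3f g/kg\n",
                nm, x[[nm]]["theta"], x[[nm]]["sa"]))
  }
  invisible(x)
}

# 3x3 mixing matrix: rows = (mass, heat, salt), columns = (ambient, runoff,
# meltwater).
mixing_matrix <- function(endmembers) {
  rbind(c(1, 1, 1),
        c(endmembers$ambient["theta"], endmembers$runoff["theta"],
          endmembers$meltwater["theta"]),
        c(endmembers$ambient["sa"], endmembers$runoff["sa"],
          endmembers$meltwater["sa"]))
}

#' Decompose samples into ambient / runoff / meltwater fractions
#'
#' Solves the exact 3x3 linear system (conservation of mass, heat, salt) per
#' sample. Fractions are not clamped; samples whose fractions fall outside
#' `[-epsilon, 1 + epsilon]` are flagged invalid, preserving diagnostic
#' information about endmember misspecification.
#'
#' @param theta conservative temperature (degC), vector
#' @param sa absolute salinity (g/kg), vector
#' @param endmembers an [endmember_set()]
#' @param epsilon validity tolerance on the fractions (default 0.02)
#' @return data.frame with columns `f_ambient`, `f_sg`, `f_melt`, `residual`,
#'   `valid`
#' @export
decompose_fractions <- function(theta, sa, endmembers, epsilon = 0.02) {
  A <- mixing_matrix(endmembers)
  if (abs(det(A)) < 1e-10) {
    stop("endmembers are collinear in (1, Theta, S_A) space; cannot decompose")
  }
  th_a <- endmembers$ambient[["theta"]]
  th_r <- endmembers$runoff[["theta"]]
  th_m <- endmembers$meltwater[["theta"]]
  s_a <- endmembers$ambient[["sa"]]
  f_ambient <- sa / s_a
  d <- 1 - f_ambient
  f_melt <- (theta - f_ambient * th_a - th_r * d) / (th_m - th_r)
  f_sg <- d - f_melt
  # diagnostic residual of the linear system (zero up to round-off)
  residual <- pmax(
    abs(f_ambient + f_sg + f_melt - 1),
    abs(f_ambient * th_a + f_sg * th_r + f_melt * th_m - theta),
    abs(f_ambient * s_a - sa)
  )
  valid <- f_ambient >= -epsilon & f_ambient <= 1 + epsilon &
    f_sg >= -epsilon & f_sg <= 1 + epsilon &
    f_melt >= -epsilon & f_melt <= 1 + epsilon
  data.frame(f_ambient = f_ambient, f_sg = f_sg, f_melt = f_melt,
             residual = residual, valid = valid)
}

#' Runoff and meltwater mixing lines
#'
#' The two segments in Theta-S_A space from the ambient endmember to the
#' runoff and meltwater endmembers, parameterised by the corresponding
#' fraction in [0, 1].
#'
#' @param endmembers an [endmember_set()]
#' @param n number of points per line
#' @return list with data.frames `runoff` and `meltwater`, each with columns
#'   `fraction`, `theta`, `sa`
#' @export
mixing_lines <- function(endmembers, n = 101) {
  f <- seq(0, 1, length.out = n)
  line_to <- function(em) {
    data.frame(fraction = f,
               theta = (1 - f) * endmembers$ambient[["theta"]] + f * em[["theta"]],
               sa = (1 - f) * endmembers$ambient[["sa"]] + f * em[["sa"]])
  }
  list(runoff = line_to(endmembers$runoff),
       meltwater = line_to(endmembers$meltwater))
}

#' Build endmembers from pre-cutoff fjord profiles
#'
#' The ambient endmember is the mean (Theta, S_A) of fjord-region samples
#' collected before `cutoff_date` within a depth band just above the
#' grounding line (default: the deepest 20 m above `reference_pressure`).
#' Runoff and meltwater endmembers follow from the thermodynamic constants.
#'
#' @param profiles a processed [profile_set()] (see [convert_teos10()]) whose
#'   dives carry a `region` column (see [classify_region()]); dives without
#'   one are classified on the fly using `geometry`
#' @param cutoff_date only dives strictly before this date contribute
#' @param geometry a [terminus_geometry()]
#' @param depth_band thickness (m) of the averaging band above the reference
#'   depth
#' @param reference_pressure grounding-line pressure (dbar)
#' @param ... constants passed to [endmember_set()]
#' @return an [endmember_set()]
#' @export
build_endmembers <- function(profiles, cutoff_date, geometry,
                             depth_band = 20, reference_pressure = 100, ...) {
  dives <- profiles$dives
  samples <- profiles$samples
  if (is.null(samples$theta) || is.null(samples$depth)) {
    stop("profiles must be TEOS-10 converted first (see convert_teos10)")
  }
  if (is.null(dives$region)) {
    dives$region <- classify_region(cbind(dives$x, dives$y), geometry)
  }
  cutoff_date <- as.POSIXct(cutoff_date, tz = "UTC")
  use_dive <- dives$region == "fjord" & dives$dive_time < cutoff_date
  if (!any(use_dive)) {
    stop("no fjord-region profiles before the cutoff date; ",
         "cannot build the ambient endmember")
  }
  ref_depth <- depth_from_pressure(reference_pressure,
                                   lat = median(dives$lat, na.rm = TRUE))
  band <- c(ref_depth - depth_band, ref_depth)
  in_band <- samples$profile_id %in% dives$profile_id[use_dive] &
    samples$depth >= band[1] & samples$depth <= band[2]
  if (!is.null(samples$flagged)) in_band <- in_band & !samples$flagged
  if (!any(in_band)) {
    stop(sprintf(paste0("no fjord-region samples before the cutoff reach the ",
                        "%.0f-%.0f m depth band; cannot build the ambient ",
                        "endmember"), band[1], band[2]))
  }
  ambient <- c(mean(samples$theta[in_band]), mean(samples$sa[in_band]))
  endmember_set(ambient, reference_pressure = reference_pressure, ...)
}

#' Detect low-salinity spikes against an ambient profile
#'
#' A sample is a spike when its absolute salinity falls more than
#' `k * sigma_s` below the ambient salinity at the same depth. A profile with
#' at least one spike is marked in-plume.
#'
#' @param samples data.frame with columns `profile_id`, `depth`, `sa`
#' @param ambient_sa_fun function of depth (m) returning ambient S_A (g/kg);
#'   see [ambient_profile_fun()]
#' @param k threshold multiplier (default 5)
#' @param sigma_s salinity uncertainty (g/kg, default 0.1)
#' @return list with `spikes` (data.frame `profile_id`, `depth`, `anomaly`)
#'   and `in_plume` (named logical, one element per profile)
#' @export
detect_salinity_spikes <- function(samples, ambient_sa_fun, k = 5,
                                   sigma_s = 0.1) {
  anomaly <- samples$sa - ambient_sa_fun(samples$depth)
  is_spike <- anomaly < -k * sigma_s
  spikes <- data.frame(profile_id = samples$profile_id[is_spike],
                       depth = samples$depth[is_spike],
                       anomaly = anomaly[is_spike])
  ids <- unique(samples$profile_id)
  in_plume <- setNames(ids %in% spikes$profile_id, ids)
  list(spikes = spikes, in_plume = in_plume, is_spike = is_spike)
}

#' Ambient salinity-vs-depth function from fjord profiles
#'
#' Bins fjord-region samples by depth (default 2 m bins), averages S_A per
#' bin and interpolates linearly, extending the end values to the surface and
#' the bottom. Used as the reference for spike detection.
#'
#' @param profiles a processed [profile_set()]
#' @param geometry a [terminus_geometry()] used to select fjord-region dives
#'   when the dives carry no `region` column
#' @param bin depth bin size (m)
#' @return function mapping depth (m) to ambient S_A (g/kg)
#' @export
ambient_profile_fun <- function(profiles, geometry = NULL, bin = 2) {
  dives <- profiles$dives
  if (is.null(dives$region)) {
    if (is.null(geometry)) stop("need either dive regions or a geometry")
    dives$region <- classify_region(cbind(dives$x, dives$y), geometry)
  }
  samples <- profiles$samples
  keep <- samples$profile_id %in% dives$profile_id[dives$region == "fjord"]
  if (!is.null(samples$flagged)) keep <- keep & !samples$flagged
  if (!any(keep)) stop("no fjord-region samples to build an ambient profile")
  zb <- floor(samples$depth[keep] / bin) * bin + bin / 2
  m <- tapply(samples$sa[keep], zb, mean)
  z <- as.numeric(names(m))
  approxfun(z, as.numeric(m), rule = 2)
}

#' Maximum subglacial discharge fraction
#'
#' The maximum `f_sg` over valid samples of in-plume profiles, with its depth
#' and profile. Returns an empty result (not an error) when no valid in-plume
#' sample exists.
#'
#' @param decomposed data.frame with columns `profile_id`, `depth`, `f_sg`,
#'   `valid` (e.g. samples joined with [decompose_fractions()] output)
#' @param in_plume named logical vector from [detect_salinity_spikes()];
#'   `NULL` means all profiles are eligible
#' @return list with `f_sg`, `depth`, `profile_id` (all `NA` when empty) and
#'   `n` (number of eligible samples)
#' @export
max_fsg <- function(decomposed, in_plume = NULL) {
  ok <- decomposed$valid
  if (!is.null(in_plume)) {
    ok <- ok & decomposed$profile_id %in% names(in_plume)[in_plume]
  }
  if (!any(ok)) {
    return(list(f_sg = NA_real_, depth = NA_real_, profile_id = NA,
                n = 0L))
  }
  i <- which(ok)[which.max(decomposed$f_sg[ok])]
  list(f_sg = decomposed$f_sg[i], depth = decomposed$depth[i],
       profile_id = decomposed$profile_id[i], n = sum(ok))
}

#' Propagated uncertainty of the decomposition fractions
#'
#' Delta-method standard deviations of the three fractions given independent
#' measurement noise on Theta and S_A (the decomposition is linear, so this
#' is exact).
#'
#' @param endmembers an [endmember_set()]
#' @param sigma_theta temperature uncertainty (degC)
#' @param sigma_sa salinity uncertainty (g/kg)
#' @return named vector of standard deviations `f_ambient`, `f_sg`, `f_melt`
#' @export
fsg_uncertainty <- function(endmembers, sigma_theta = 0.02, sigma_sa = 0.1) {
  Ainv <- solve(mixing_matrix(endmembers))
  # columns of Ainv multiply (1, Theta, S_A); noise enters rows 2 and 3
  sds <- sqrt((Ainv[, 2] * sigma_theta)^2 + (Ainv[, 3] * sigma_sa)^2)
  setNames(as.numeric(sds), c("f_ambient", "f_sg", "f_melt"))
}
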