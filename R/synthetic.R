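# Synthetic study generator: a stratified ambient fjord, a buoyant
# entrainment plume whose strength tracks a daily runoff series, seals that
# preferentially dive near the active plume, ascent-sampled profiles with
# instrument noise, 4-hour deepest-dive transmission, and a mix of GPS and
# interpolated dive locations. A truth record makes every downstream check
# closed-loop.

#' Synthetic campaign configuration
#'
#' Defaults reproduce the study conditions: five seals over August-December
#' 2012, a 100 m deep terminus, runoff peaks of 150, 220 and 70 m^3/s,
#' sensor noise of 0.02 degC and 0.1 g/kg, one transmitted dive per 4-hour
#' block, and a plume calibrated so the strongest core encounter reaches a
#' subglacial discharge fraction of 0.27 at 64 m depth.
#'
#' @param n_seals number of instrumented seals
#' @param start,end campaign date range (`Date`)
#' @param terminus_depth grounding-line depth at the plume source (m)
#' @param runoff_peaks data.frame with `day` (`Date`), `amplitude` (m^3/s)
#'   and `width` (days) of Gaussian runoff pulses
#' @param runoff_baseline baseline discharge (m^3/s)
#' @param ambient_surface,ambient_bottom `c(theta, sa)` at the surface and at
#'   depth
#' @param pycnocline_depth depth (m) below which the ambient column is
#'   uniform; stratification is linear above it
#' @param noise logical: add instrument noise
#' @param sigma_t,sigma_s noise standard deviations (degC, salinity units)
#' @param near_terminus_base_prob probability per 4-h block of a dive near
#'   the plume source when runoff is zero
#' @param near_terminus_gain added probability per unit normalised runoff
#' @param response_exponent exponent applied to the normalised runoff in the
#'   behavioural response (`p = base + gain * (Q/Qmax)^response_exponent`);
#'   the default 0.5 encodes a saturating response — real seals cluster
#'   almost as densely at modest discharge as at the seasonal maximum
#' @param near_terminus_diffuse_prob probability of a dive placed diffusely
#'   within the near-terminus buffer irrespective of runoff: seals keep a
#'   general affinity for the glacier front even when no plume is active,
#'   without forming the tight at-source clusters that the sweep statistic
#'   detects
#' @param visit_model `"quota"` realises the behavioural response as the
#'   rounded expected number of plume visits per day (assigned by per-dive
#'   uniform ranks), so daily visit counts track the runoff exactly;
#'   `"bernoulli"` draws each dive's destination independently with the same
#'   probabilities
#' @param plume_scatter horizontal scatter scale (m) of near-plume dives
#'   beyond the closest-approach radius
#' @param fsg_max,fsg_max_depth configured maximum core subglacial discharge
#'   fraction and the depth (m) at which it is attained
#' @param transmission_block_hours transmission block length (h)
#' @param p_transmit probability that a block's deepest dive is actually
#'   relayed through the satellite link (delivery is lossy; about 0.2
#'   reproduces the few profiles per seal-day of real deployments)
#' @param p_interp probability that a dive location is interpolated rather
#'   than GPS-derived
#' @param p_value_interp probability that a profile contains an interpolated
#'   salinity value (exercises the exclusion rule)
#' @param plume_source optional (x, y) of the subglacial source on the
#'   terminus line (default: midpoint of the Kronebreen-like front)
#' @param entrainment plume entrainment coefficient
#' @param w0 source vertical velocity (m/s) for the plume model; `NULL` means
#'   the momentum-balanced value (see [build_plume_field()])
#' @param plume_min_flux discharge (m^3/s) below which the plume is
#'   considered off
#' @param seed master RNG seed
#' @return named list of class `synthetic_config`
#' @export
synthetic_config <- function(n_seals = 5,
                             start = as.Date("2012-08-01"),
                             end = as.Date("2012-12-31"),
                             terminus_depth = 100,
                             runoff_peaks = data.frame(
                               day = as.Date(c("2012-08-08", "2012-08-26",
                                               "2012-09-12")),
                               amplitude = c(150, 220, 70),
                               width = c(2, 3, 2)),
                             runoff_baseline = 0,
                             ambient_surface = c(theta = 5.0, sa = 31.5),
                             ambient_bottom = c(theta = 2.8, sa = 34.3),
                             pycnocline_depth = 40,
                             noise = TRUE, sigma_t = 0.02, sigma_s = 0.1,
                             near_terminus_base_prob = 0.05,
                             near_terminus_gain = 0.85,
                             response_exponent = 0.5,
                             near_terminus_diffuse_prob = 0.25,
                             visit_model = c("quota", "bernoulli"),
                             plume_scatter = 100,
                             fsg_max = 0.27, fsg_max_depth = 64,
                             transmission_block_hours = 4,
                             p_transmit = 0.25,
                             p_interp = 0.3, p_value_interp = 0.02,
                             plume_source = NULL,
                             entrainment = 0.1, w0 = NULL,
                             plume_min_flux = 0.5,
                             seed = 1L) {
  visit_model <- match.arg(visit_model)
  stopifnot(n_seals >= 1, end >= start, terminus_depth > 0,
            all(runoff_peaks$amplitude >= 0), all(runoff_peaks$width > 0),
            runoff_baseline >= 0,
            near_terminus_base_prob >= 0, near_terminus_base_prob <= 1,
            near_terminus_gain >= 0, response_exponent > 0,
            near_terminus_diffuse_prob >= 0, near_terminus_diffuse_prob <= 1,
            near_terminus_base_prob + near_terminus_gain <= 1,
            sigma_t >= 0, sigma_s >= 0,
            p_transmit > 0, p_transmit <= 1,
            p_interp >= 0, p_interp <= 1,
            p_value_interp >= 0, p_value_interp <= 1,
            fsg_max > 0, fsg_max < 1,
            fsg_max_depth > 0, fsg_max_depth < terminus_depth,
            entrainment > 0,
            transmission_block_hours > 0, 24 %% transmission_block_hours == 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate the daily runoff series
#'
#' Baseline plus a sum of Gaussian pulses, clipped at zero.
#'
#' @param config a [synthetic_config()]
#' @return data.frame with `day` (`Date`) and `discharge` (m^3/s)
#' @export
generate_runoff_series <- function(config) {
  days <- seq(config$start, config$end, by = "day")
  if (!length(days)) stop("empty date range in configuration")
  q <- rep(config$runoff_baseline, length(days))
  pk <- config$runoff_peaks
  for (i in seq_len(nrow(pk))) {
    dt <- as.numeric(days - pk$day[i])
    q <- q + pk$amplitude[i] * exp(-0.5 * (dt / pk$width[i])^2)
  }
  data.frame(day = days, discharge = pmax(0, q))
}

#' Axisymmetric entrainment plume field
#'
#' Integrates the classical entrainment-plume equations for volume flux `Q`
#' and momentum flux `M` in an unstratified ambient (buoyancy flux
#' conserved): `dQ/dz = 2 alpha sqrt(pi M)`, `dM/dz = F Q / M` with
#' `F = Q0 g'`. The core dilution is `f_core(z) = Q0 / Q(z)` (capped at 1)
#' and the Gaussian radial scale is `b(z) = Q / sqrt(pi M)`. A zero source
#' flux yields `f_core == 0`.
#'
#' @param source_flux subglacial discharge (m^3/s), >= 0
#' @param terminus_depth source depth (m)
#' @param entrainment entrainment coefficient (default 0.1)
#' @param w0 source vertical velocity (m/s); `NULL` (default) selects the
#'   momentum-balanced value `(g' sqrt(Q0) / (4 alpha sqrt(pi)))^(2/5)`, for
#'   which the plume radius is non-decreasing from the source upward
#' @param gprime source reduced gravity (m/s^2); default from fresh vs
#'   34.3 g/kg water
#' @param dz integration step (m), <= 0.5
#' @return object of class `plume_field`: functions `f_core(h)` and `b(h)` of
#'   height `h` above the source, the solution grid, and the parameters
#' @export
build_plume_field <- function(source_flux, terminus_depth,
                              entrainment = 0.1, w0 = NULL,
                              gprime = NULL, dz = 0.5) {
  if (source_flux < 0) stop("source_flux must be non-negative")
  stopifnot(terminus_depth > 0, entrainment > 0, dz <= 0.5, dz > 0)
  if (is.null(gprime)) {
    drho <- sigma0(sp_from_sa(34.3), 2.8) - sigma0(0, 0)
    gprime <- 9.81 * drho / 1000
  }
  if (is.null(w0)) {
    w0 <- if (source_flux > 0) {
      (gprime * sqrt(source_flux) / (4 * entrainment * sqrt(pi)))^(2 / 5)
    } else 1
  }
  stopifnot(w0 > 0)
  h <- seq(0, terminus_depth, by = dz)
  if (source_flux == 0) {
    return(structure(list(
      h = h, f_core = rep(0, length(h)), b = rep(1e-6, length(h)),
      f_core_fun = function(z) rep(0, length(z)),
      b_fun = function(z) rep(1e-6, length(z)),
      source_flux = 0, terminus_depth = terminus_depth,
      entrainment = entrainment, w0 = w0, gprime = gprime
    ), class = "plume_field"))
  }
  Q0 <- source_flux
  F0 <- Q0 * gprime
  deriv <- function(t, y, parms) {
    list(c(Q = 2 * parms$alpha * sqrt(pi * y[2]),
           M = parms$F0 * y[1] / y[2]))
  }
  sol <- deSolve::ode(y = c(Q = Q0, M = Q0 * w0), times = h, func = deriv,
                      parms = list(alpha = entrainment, F0 = F0),
                      method = "rk4")
  Q <- sol[, "Q"]; M <- sol[, "M"]
  f_core <- pmin(1, Q0 / Q)
  b <- Q / sqrt(pi * M)
  structure(list(
    h = h, f_core = f_core, b = b,
    f_core_fun = approxfun(h, f_core, rule = 2),
    b_fun = approxfun(h, b, rule = 2),
    source_flux = source_flux, terminus_depth = terminus_depth,
    entrainment = entrainment, w0 = w0, gprime = gprime
  ), class = "plume_field")
}

#' @export
print.plume_field <- function(x, ...) {
  cat(sprintf("Plume field: source %g m^3/s at %g m depth, alpha = %g\n",
              x$source_flux, x$terminus_depth, x$entrainment))
  if (x$source_flux > 0) {
    cat(sprintf("  at the surface: f_core = %.3f, b = %.1f m\n",
                x$f_core[length(x$f_core)], x$b[length(x$b)]))
  }
  invisible(x)
}

# Local subglacial-discharge fraction at depth z (m) and horizontal distance
# r (m) from the plume axis: Gaussian radial structure on the core dilution.
plume_fsg_at <- function(field, z, r) {
  h <- field$terminus_depth - z
  f <- field$f_core_fun(h) * exp(-(r / field$b_fun(h))^2)
  f[h < 0] <- 0
  f
}

# Smallest approach radius at which the local f_sg stays at or below `fcap`
# at every height of the field (envelope of the Gaussian radial profile).
.plume_min_radius <- function(field, fcap) {
  ok <- field$f_core > fcap
  if (!any(ok)) return(0)
  max(field$b[ok] * sqrt(log(field$f_core[ok] / fcap)))
}

#' Calibrate the plume source to a target core encounter
#'
#' Finds the source flux (as a fraction of the peak catchment runoff routed
#' through the subglacial outlet) such that the plume's core dilution at
#' `target_depth` equals `target_fsg`: a dive terminating at that depth on
#' the plume axis then samples exactly the configured maximum subglacial
#' discharge fraction, at that depth, as the deepest and freshest point of
#' its ascent profile. Used by [simulate_campaign()] so that the configured
#' maximum is exactly recoverable downstream.
#'
#' @param peak_runoff catchment runoff (m^3/s) at which the target is
#'   attained
#' @param terminus_depth source depth (m)
#' @param target_fsg,target_depth the target maximum and its depth (m)
#' @param entrainment entrainment coefficient
#' @param w0 source vertical velocity (m/s); `NULL` = momentum-balanced
#' @param gprime source reduced gravity (m/s^2), see [build_plume_field()]
#' @return list with `source_fraction` (source flux / catchment runoff),
#'   `flux` (m^3/s) and the calibrated `field` at the peak
#' @export
calibrate_plume <- function(peak_runoff, terminus_depth,
                            target_fsg = 0.27, target_depth = 64,
                            entrainment = 0.1, w0 = NULL, gprime = NULL) {
  stopifnot(peak_runoff > 0, target_depth < terminus_depth,
            target_fsg > 0, target_fsg < 1)
  h_target <- terminus_depth - target_depth
  fcore_at <- function(q0) {
    field <- build_plume_field(q0, terminus_depth, entrainment = entrainment,
                               w0 = w0, gprime = gprime)
    field$f_core_fun(h_target)
  }
  # core dilution at fixed height strengthens as the source flux shrinks
  g <- function(q0) fcore_at(q0) - target_fsg
  lo <- 1e-3 * peak_runoff
  if (g(lo) > 0) stop("target f_sg unreachable: dilution too weak even for ",
                      "a tiny source")
  hi <- peak_runoff
  while (g(hi) < 0 && hi < 100 * peak_runoff) hi <- hi * 2
  if (g(hi) < 0) stop("target f_sg unreachable at this depth")
  q0 <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  field <- build_plume_field(q0, terminus_depth, entrainment = entrainment,
                             w0 = w0, gprime = gprime)
  list(source_fraction = q0 / peak_runoff, flux = q0, field = field)
}

# Ambient stratification: linear between the surface pair and the bottom pair
# down to the pycnocline depth, uniform below. Returns a function of depth
# giving cbind(theta, sa).
make_ambient_fun <- function(config) {
  zs <- config$pycnocline_depth
  s0 <- config$ambient_surface; s1 <- config$ambient_bottom
  function(z) {
    w <- pmin(1, pmax(0, z / zs))
    cbind(theta = (1 - w) * s0[["theta"]] + w * s1[["theta"]],
          sa = (1 - w) * s0[["sa"]] + w * s1[["sa"]])
  }
}

#' Sample an ascent profile at a point in the plume field
#'
#' At each depth the local subglacial discharge fraction is
#' `f = f_core(z) * exp(-r^2 / b(z)^2)`; the sample is the convex combination
#' of the runoff endmember and the ambient column at that depth, converted to
#' instrument variables (in-situ temperature, practical salinity, pressure)
#' with optional Gaussian noise.
#'
#' @param point `c(x, y)` of the dive (projected m)
#' @param field a [build_plume_field()] result (its source position is
#'   supplied via `source_xy`)
#' @param source_xy `c(x, y)` of the plume source
#' @param ambient_fun function of depth returning `cbind(theta, sa)`, see the
#'   configuration's stratification
#' @param endmembers an [endmember_set()] providing the runoff endmember
#' @param depths sample depths (m), e.g. `1:dive_depth` (1 m ascent
#'   resolution)
#' @param lat latitude (degrees) for the pressure conversion
#' @param noise logical; add instrument noise
#' @param sigma_t,sigma_s noise standard deviations
#' @return data.frame with `pressure`, `temp_insitu`, `psal` and truth
#'   columns `depth`, `theta_true`, `sa_true`, `fsg_true`
#' @export
sample_profile_at <- function(point, field, source_xy, ambient_fun,
                              endmembers, depths, lat = 79,
                              noise = TRUE, sigma_t = 0.02, sigma_s = 0.1) {
  r <- sqrt(sum((point - source_xy)^2))
  f <- plume_fsg_at(field, depths, r)
  amb <- ambient_fun(depths)
  theta <- f * endmembers$runoff[["theta"]] + (1 - f) * amb[, "theta"]
  sa <- f * endmembers$runoff[["sa"]] + (1 - f) * amb[, "sa"]
  p <- pressure_from_depth(depths, lat)
  psal <- sp_from_sa(sa)
  t_insitu <- insitu_from_ct(psal, theta, p)
  if (noise) {
    t_insitu <- t_insitu + rnorm(length(depths), 0, sigma_t)
    psal <- psal + rnorm(length(depths), 0, sigma_s)
  }
  data.frame(pressure = p, temp_insitu = t_insitu, psal = psal,
             depth = depths, theta_true = theta, sa_true = sa, fsg_true = f)
}

# uniform point inside the fjord polygon (bounded rejection sampling)
.uniform_in_fjord <- function(geometry) {
  fj <- geometry$fjord
  xr <- range(fj[, 1]); yr <- range(fj[, 2])
  for (i in 1:100) {
    p <- c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]))
    if (in_fjord(p, geometry)[1]) return(p)
  }
  colMeans(fj)  # unreachable for sane polygons
}

# uniform point inside the near-terminus buffer of the marine-terminating
# front (bounded rejection sampling)
.uniform_in_buffer <- function(geometry) {
  kr <- geometry$kronebreen
  b <- geometry$buffer_distance
  xr <- range(kr[, 1]) + c(-b, b); yr <- range(kr[, 2]) + c(-b, b)
  for (i in 1:200) {
    p <- c(runif(1, xr[1], xr[2]), runif(1, yr[1], yr[2]))
    if (dist_to_polyline(p, kr)[1] <= b && in_fjord(p, geometry)[1]) return(p)
  }
  kr[1, ]  # unreachable for sane geometries
}

#' Simulate a full synthetic campaign
#'
#' Per seal and 4-hour block one transmitted dive: with probability
#' `base_prob + gain * Q_day / Q_max` the dive is placed near the active
#' plume source (at the calibrated closest-approach radius plus an
#' exponential scatter), otherwise uniformly in the fjord. Ascent profiles
#' are sampled at 1 m resolution through the plume field of the day's
#' discharge. On the day of maximum runoff one designated dive is placed
#' exactly at the closest-approach radius, so the campaign's true maximum
#' f_sg equals the configured target. Each dive uses its own derived RNG
#' substream, which makes the campaign reproducible and the near-terminus
#' fraction monotone in the behavioural gain at a fixed seed.
#'
#' @param config a [synthetic_config()]
#' @param runoff optional runoff series (default [generate_runoff_series()])
#' @param geometry a [terminus_geometry()] (default
#'   [synthetic_fjord_geometry()])
#' @return list with `profiles` (a [profile_set()], samples carry truth
#'   columns), `fixes` (GPS fix table), `runoff`, `truth` (per-dive truth
#'   table, calibration, plume-active days, config echo) and `geometry`
#' @export
simulate_campaign <- function(config = synthetic_config(), runoff = NULL,
                              geometry = synthetic_fjord_geometry()) {
  if (is.null(geometry$fjord)) stop("geometry with a fjord polygon is required")
  if (is.null(runoff)) runoff <- generate_runoff_series(config)
  stopifnot(all(runoff$discharge >= 0))
  days <- runoff$day
  q <- runoff$discharge
  qmax <- max(q)
  lat0 <- mean(utm_unproject(mean(geometry$fjord[, 1]),
                             mean(geometry$fjord[, 2]),
                             zone = geometry$zone)[, "lat"])
  ref_p <- pressure_from_depth(config$terminus_depth, lat0)
  em <- endmember_set(c(config$ambient_bottom[["theta"]],
                        config$ambient_bottom[["sa"]]),
                      reference_pressure = ref_p)
  ambient_fun <- make_ambient_fun(config)
  gprime <- 9.81 * (sigma0(sp_from_sa(config$ambient_bottom[["sa"]]),
                           config$ambient_bottom[["theta"]]) -
                    sigma0(0, em$runoff[["theta"]])) / 1000

  source_xy <- config$plume_source
  if (is.null(source_xy)) {
    kr <- geometry$kronebreen
    source_xy <- c(mean(range(kr[, 1])), mean(range(kr[, 2])))
  }
  # inward normal: from the source toward the fjord centroid
  ctr <- colMeans(geometry$fjord)
  nrm <- ctr - source_xy
  nrm <- nrm / sqrt(sum(nrm^2))

  plume_on <- q > config$plume_min_flux
  cal <- NULL
  fields <- list()
  rmins <- rep(NA_real_, length(days))
  if (any(plume_on)) {
    cal <- calibrate_plume(qmax, config$terminus_depth,
                           target_fsg = config$fsg_max,
                           target_depth = config$fsg_max_depth,
                           entrainment = config$entrainment,
                           w0 = config$w0, gprime = gprime)
    for (d in which(plume_on)) {
      fields[[d]] <- build_plume_field(cal$source_fraction * q[d],
                                       config$terminus_depth,
                                       entrainment = config$entrainment,
                                       w0 = config$w0, gprime = gprime)
      # non-designated dives keep a margin below the configured maximum
      rmins[d] <- .plume_min_radius(fields[[d]], 0.9 * config$fsg_max)
    }
  }
  designated_day <- if (any(plume_on)) which.max(q) else NA_integer_

  blocks_per_day <- as.integer(24 / config$transmission_block_hours)
  grid <- expand.grid(blk = seq_len(blocks_per_day),
                      seal = seq_len(config$n_seals),
                      d = seq_along(days))
  n_dives <- nrow(grid)

  # pass 1: per-dive decision draws (block-time offset, transmission, visit
  # rank) from each dive's own substream
  dec <- matrix(0, n_dives, 3)
  for (i in seq_len(n_dives)) {
    dec[i, ] <- with_seed(derive_seed(config$seed, i), runif(3))
  }
  designated <- !is.na(designated_day) & grid$d == designated_day &
    grid$seal == 1L & grid$blk == max(1L, blocks_per_day %/% 2L)
  transmitted <- dec[, 2] < config$p_transmit | designated
  u <- dec[, 3]

  # pass 2: destination of every transmitted dive
  mode <- rep("uniform", n_dives)
  for (d in seq_along(days)) {
    sel <- which(transmitted & grid$d == d)
    if (!length(sel)) next
    p_tight <- if (plume_on[d] && qmax > 0) {
      config$near_terminus_base_prob + config$near_terminus_gain *
        (q[d] / qmax)^config$response_exponent
    } else 0
    if (config$visit_model == "quota") {
      ord <- sel[order(u[sel])]
      k <- round(p_tight * length(sel))
      m <- round(config$near_terminus_diffuse_prob * length(sel))
      if (k > 0) mode[ord[seq_len(min(k, length(ord)))]] <- "plume"
      rest <- if (k > 0) ord[-seq_len(min(k, length(ord)))] else ord
      if (m > 0 && length(rest)) {
        mode[rest[seq_len(min(m, length(rest)))]] <- "diffuse"
      }
    } else {
      pl <- u[sel] < p_tight
      df <- !pl & u[sel] < p_tight + config$near_terminus_diffuse_prob
      mode[sel[pl]] <- "plume"
      mode[sel[df]] <- "diffuse"
    }
  }
  mode[designated] <- "plume"

  # pass 3: placement, ascent profile, fixes (second per-dive substream)
  dive_rows <- vector("list", n_dives)
  sample_rows <- vector("list", n_dives)
  fix_rows <- vector("list", n_dives)
  for (i in which(transmitted)) {
    d <- grid$d[i]
    res <- with_seed(derive_seed(config$seed, i + n_dives), {
      .simulate_one_dive(i, d, grid$seal[i], grid$blk[i], days, dec[i, 1],
                         mode[i], designated[i], fields, source_xy, nrm,
                         rmins[d], geometry, config, ambient_fun, em, lat0)
    })
    dive_rows[[i]] <- res$dive
    sample_rows[[i]] <- res$samples
    fix_rows[[i]] <- res$fixes
  }
  dives <- do.call(rbind, dive_rows)
  samples <- do.call(rbind, sample_rows)
  fixes <- do.call(rbind, fix_rows)
  fixes <- fixes[order(fixes$seal_id, fixes$time), , drop = FALSE]

  # consecutive-interpolation run lengths per seal, in time order; every dive
  # in a run carries the run's total length
  dives <- dives[order(dives$seal_id, dives$dive_time), , drop = FALSE]
  dives$interp_run_length <- 0L
  for (s in unique(dives$seal_id)) {
    i <- which(dives$seal_id == s)
    r <- rle(dives$location_source[i] == "interpolated")
    run_len <- rep(r$lengths, r$lengths) * rep(r$values, r$lengths)
    dives$interp_run_length[i] <- as.integer(run_len)
  }

  truth_cols <- c("profile_id", "true_x", "true_y", "true_region",
                  "true_max_fsg", "plume_visit", "designated")
  truth_dives <- dives[, truth_cols]
  dives <- dives[, setdiff(names(dives), setdiff(truth_cols, "profile_id"))]
  profiles <- profile_set(dives, samples)
  list(profiles = profiles, fixes = fixes, runoff = runoff,
       geometry = geometry,
       truth = list(dives = truth_dives,
                    plume_active_days = days[plume_on],
                    calibration = list(
                      entrainment = config$entrainment,
                      source_fraction = if (is.null(cal)) NA_real_ else
                        cal$source_fraction,
                      peak_source_flux = if (is.null(cal)) NA_real_ else
                        cal$flux,
                      designated_day = if (is.na(designated_day)) NA else
                        days[designated_day]),
                    endmembers = em,
                    fsg_max = config$fsg_max,
                    fsg_max_depth = config$fsg_max_depth,
                    seed = config$seed))
}

# One transmitted dive: placement, profile, fixes. Runs inside the dive's own
# RNG substream.
.simulate_one_dive <- function(idx, d, seal, blk, days, t0frac, mode,
                               designated, fields, source_xy, nrm, r_min,
                               geometry, config, ambient_fun, em, lat0) {
  block_h <- config$transmission_block_hours
  t0 <- as.POSIXct(days[d], tz = "UTC") + ((blk - 1) + t0frac) * block_h * 3600
  plume_visit <- mode == "plume"
  if (plume_visit) {
    if (designated) {
      pos <- source_xy  # on the plume axis: the core encounter
      dive_depth <- config$fsg_max_depth
    } else {
      r <- r_min + rexp(1, rate = 1 / config$plume_scatter)
      ang <- atan2(nrm[2], nrm[1]) + runif(1, -80, 80) * pi / 180
      pos <- source_xy + r * c(cos(ang), sin(ang))
      if (!in_fjord(pos, geometry)[1]) pos <- source_xy + r * nrm
      dive_depth <- config$terminus_depth - round(runif(1, 0, 5))
    }
  } else if (mode == "diffuse") {
    pos <- .uniform_in_buffer(geometry)
    dive_depth <- config$terminus_depth - round(runif(1, 0, 20))
  } else {
    pos <- .uniform_in_fjord(geometry)
    dive_depth <- config$terminus_depth - round(runif(1, 0, 40))
  }
  depths <- seq_len(dive_depth)
  field <- if (d <= length(fields)) fields[[d]] else NULL
  if (!is.null(field)) {
    smp <- sample_profile_at(pos, field, source_xy, ambient_fun, em, depths,
                             lat = lat0, noise = config$noise,
                             sigma_t = config$sigma_t,
                             sigma_s = config$sigma_s)
  } else {
    amb <- ambient_fun(depths)
    p <- pressure_from_depth(depths, lat0)
    psal <- sp_from_sa(amb[, "sa"])
    t_insitu <- insitu_from_ct(psal, amb[, "theta"], p)
    if (config$noise) {
      t_insitu <- t_insitu + rnorm(length(depths), 0, config$sigma_t)
      psal <- psal + rnorm(length(depths), 0, config$sigma_s)
    }
    smp <- data.frame(pressure = p, temp_insitu = t_insitu, psal = psal,
                      depth = depths, theta_true = amb[, "theta"],
                      sa_true = amb[, "sa"], fsg_true = 0)
  }
  pid <- sprintf("d%05d", idx)
  smp$profile_id <- pid
  smp$interp_t <- FALSE
  smp$interp_s <- FALSE
  if (runif(1) < config$p_value_interp && nrow(smp) > 2 && !designated) {
    smp$interp_s[sample(nrow(smp), 1)] <- TRUE
  }
  interp <- runif(1) < config$p_interp && !designated
  loc_err <- if (interp) 30 else 10
  obs <- pos + rnorm(2, 0, loc_err)
  ll <- utm_unproject(obs[1], obs[2], zone = geometry$zone)
  dive <- data.frame(
    profile_id = pid, seal_id = sprintf("seal%02d", seal), dive_time = t0,
    lon = ll[1, "lon"], lat = ll[1, "lat"], x = obs[1], y = obs[2],
    location_source = if (interp) "interpolated" else "gps",
    interp_run_length = 0L,
    true_x = pos[1], true_y = pos[2],
    true_region = classify_region(pos, geometry),
    true_max_fsg = max(smp$fsg_true),
    plume_visit = plume_visit, designated = designated
  )
  fixes <- NULL
  if (!interp) {
    dtf <- runif(2, 300, 2400)  # 5-40 min before/after
    fx <- obs[1] + rnorm(2, 0, 15); fy <- obs[2] + rnorm(2, 0, 15)
    fll <- utm_unproject(fx, fy, zone = geometry$zone)
    fixes <- data.frame(seal_id = dive$seal_id,
                        time = t0 + c(-dtf[1], dtf[2]),
                        lon = fll[, "lon"], lat = fll[, "lat"],
                        x = fx, y = fy, source = "gps")
  }
  list(dive = dive, samples = smp, fixes = fixes)
}
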