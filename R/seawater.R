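# Compact seawater thermodynamics for fjord CTD work.
#
# Variables follow the TEOS-10 naming convention (absolute salinity S_A in
# g/kg, conservative temperature Theta in degrees C) but are computed with the
# classical, fully published UNESCO/Fofonoff formulas plus the
# reference-composition salinity rescaling:
#
#   * S_A = S_P * (35.16504 / 35)          (SAAR anomaly neglected; it is
#     below 0.01 g/kg in Arctic shelf water, far under the 0.1 g/kg sensor
#     accuracy relevant here)
#   * Theta is estimated by potential temperature referenced to the surface
#     (UNESCO 1983 adiabatic lapse rate, 4th-order Runge-Kutta); the
#     Theta - theta distinction is below 0.05 degC over the salinity and
#     temperature ranges of a glacial fjord.
#   * depth/pressure via the UNESCO 1983 formula with latitude-dependent
#     gravity; freezing point via Millero (UNESCO 1983); density at 0 dbar
#     via the UNESCO one-atmosphere equation of state.
#
# Published check values for all of these are frozen in the test suite.

# g/kg of Absolute Salinity per unit of Practical Salinity (TEOS-10 u_PS)
.sa_per_sp <- 35.16504 / 35

#' Absolute salinity from practical salinity
#'
#' Reference-composition scaling `S_A = S_P * 35.16504/35`. The regional
#' salinity anomaly is neglected, which is accurate to well under the sensor
#' noise in coastal Arctic water.
#'
#' @param sp practical salinity (PSS-78, dimensionless)
#' @return absolute salinity in g/kg
#' @export
sa_from_sp <- function(sp) {
  sp * .sa_per_sp
}

#' Practical salinity from absolute salinity
#' @param sa absolute salinity (g/kg)
#' @return practical salinity (PSS-78)
#' @export
sp_from_sa <- function(sa) {
  sa / .sa_per_sp
}

#' Adiabatic temperature gradient
#'
#' UNESCO 1983 (Fofonoff & Millard) polynomial; used by the potential
#' temperature integration.
#'
#' @param s practical salinity
#' @param t in-situ temperature (degC, ITS-90 treated as IPTS-68 compatible
#'   at this accuracy)
#' @param p sea pressure (dbar)
#' @return lapse rate in degC/dbar
#' @export
adiabatic_lapse_rate <- function(s, t, p) {
  ds <- s - 35
  (3.5803e-5 + (8.5258e-6 + (-6.836e-8 + 6.6228e-10 * t) * t) * t) +
    (1.8932e-6 - 4.2393e-8 * t) * ds +
    ((1.8741e-8 + (-6.7795e-10 + (8.733e-12 - 5.4481e-14 * t) * t) * t) +
       (-1.1351e-10 + 2.7759e-12 * t) * ds) * p +
    (-4.6206e-13 + (1.8676e-14 - 2.1687e-16 * t) * t) * p * p
}

#' Potential temperature
#'
#' Temperature a parcel at (`s`, `t`, `p`) would have if moved adiabatically
#' to reference pressure `p_ref`. UNESCO 1983 Runge-Kutta integration of the
#' adiabatic lapse rate. Vectorised over samples.
#'
#' @param s practical salinity
#' @param t in-situ temperature (degC)
#' @param p sea pressure (dbar)
#' @param p_ref reference pressure (dbar), default 0 (surface)
#' @return potential temperature (degC)
#' @export
potential_temperature <- function(s, t, p, p_ref = 0) {
  dp <- p_ref - p
  dth <- dp * adiabatic_lapse_rate(s, t, p)
  th <- t + 0.5 * dth
  q <- dth
  dth <- dp * adiabatic_lapse_rate(s, th, p + 0.5 * dp)
  th <- th + (1 - 1 / sqrt(2)) * (dth - q)
  q <- (2 - sqrt(2)) * dth + (-2 + 3 / sqrt(2)) * q
  dth <- dp * adiabatic_lapse_rate(s, th, p + 0.5 * dp)
  th <- th + (1 + 1 / sqrt(2)) * (dth - q)
  q <- (2 + sqrt(2)) * dth + (-2 - 3 / sqrt(2)) * q
  dth <- dp * adiabatic_lapse_rate(s, th, p + dp)
  th + (dth - 2 * q) / 6
}

#' Conservative temperature (estimate) from in-situ temperature
#'
#' Returns the surface-referenced potential temperature as the package's
#' estimate of TEOS-10 conservative temperature. At fjord pressures
#' (< a few hundred dbar) and polar temperatures the difference is below the
#' instrument accuracy of seal-borne CTDs.
#'
#' @param sp practical salinity
#' @param t in-situ temperature (degC)
#' @param p sea pressure (dbar)
#' @return conservative temperature Theta (degC)
#' @export
ct_from_insitu <- function(sp, t, p) {
  potential_temperature(sp, t, p, p_ref = 0)
}

#' In-situ temperature from conservative temperature
#'
#' Inverse of [ct_from_insitu()]: the lapse-rate integration run from the
#' surface down to pressure `p`. Round-trips with [ct_from_insitu()] to
#' ~1e-6 degC.
#'
#' @param sp practical salinity
#' @param ct conservative temperature (degC)
#' @param p sea pressure (dbar)
#' @return in-situ temperature (degC)
#' @export
insitu_from_ct <- function(sp, ct, p) {
  potential_temperature(sp, ct, 0, p_ref = p)
}

# latitude-dependent surface gravity (UNESCO 1983), m/s^2
.gravity <- function(lat) {
  x <- sin(lat * pi / 180)^2
  9.780318 * (1 + (5.2788e-3 + 2.36e-5 * x) * x)
}

#' Depth from sea pressure
#'
#' UNESCO 1983 formula with latitude-dependent gravity.
#'
#' @param p sea pressure (dbar)
#' @param lat latitude (degrees)
#' @return depth (m, positive down)
#' @export
depth_from_pressure <- function(p, lat = 79) {
  poly <- ((((-1.82e-15 * p + 2.279e-10) * p - 2.2512e-5) * p + 9.72659) * p)
  poly / (.gravity(lat) + 1.092e-6 * p)
}

#' Sea pressure from depth
#'
#' Numerical inverse of [depth_from_pressure()] (Newton iterations; exact to
#' ~1e-8 dbar at fjord depths).
#'
#' @param z depth (m, positive down)
#' @param lat latitude (degrees)
#' @return sea pressure (dbar)
#' @export
pressure_from_depth <- function(z, lat = 79) {
  p <- z * 1.01  # close initial guess near the surface
  for (i in 1:6) {
    f <- depth_from_pressure(p, lat) - z
    # derivative by small central difference; the formula is smooth
    df <- (depth_from_pressure(p + 1e-3, lat) -
             depth_from_pressure(p - 1e-3, lat)) / 2e-3
    p <- p - f / df
  }
  p
}

#' Freezing temperature of seawater
#'
#' Millero (UNESCO 1983) freezing point, converted to surface-referenced
#' potential temperature so that it is directly comparable with
#' [ct_from_insitu()] output. Accepts absolute salinity.
#'
#' @param sa absolute salinity (g/kg)
#' @param p sea pressure (dbar)
#' @return freezing temperature as Theta (degC)
#' @export
freezing_temperature <- function(sa, p = 0) {
  stopifnot(all(sa >= 0), all(p >= 0))
  sp <- sp_from_sa(sa)
  tf <- -0.0575 * sp + 1.710523e-3 * sp^1.5 - 2.154996e-4 * sp^2 - 7.53e-4 * p
  potential_temperature(sp, tf, p, p_ref = 0)
}

# in-situ freezing temperature (not referenced); used by tests
freezing_temperature_insitu <- function(sp, p = 0) {
  -0.0575 * sp + 1.710523e-3 * sp^1.5 - 2.154996e-4 * sp^2 - 7.53e-4 * p
}

#' Potential density anomaly at 0 dbar
#'
#' UNESCO 1983 one-atmosphere equation of state evaluated at the potential
#' temperature, minus 1000 kg/m^3. Used by the density-inversion QC test.
#'
#' @param sp practical salinity
#' @param theta potential/conservative temperature (degC)
#' @return sigma-0 (kg/m^3)
#' @export
sigma0 <- function(sp, theta) {
  t <- theta
  rw <- 999.842594 + (6.793952e-2 + (-9.095290e-3 + (1.001685e-4 +
        (-1.120083e-6 + 6.536332e-9 * t) * t) * t) * t) * t
  a <- 0.824493 + (-4.0899e-3 + (7.6438e-5 + (-8.2467e-7 + 5.3875e-9 * t) * t) * t) * t
  b <- -5.72466e-3 + (1.0227e-4 - 1.6546e-6 * t) * t
  c0 <- 4.8314e-4
  rw + a * sp + b * sp^1.5 + c0 * sp^2 - 1000
}
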