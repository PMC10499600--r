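#' Physical constants used throughout the package
#'
#' A fixed list of physical constants on SI units: the molar gas constant
#' \code{R_gas} (J K^-1 mol^-1, the exact CODATA product k_B * N_A,
#' approximately 8.3145), Avogadro's number \code{N_A} (mol^-1),
#' Boltzmann's constant \code{k_B} (J K^-1), the incubation temperature
#' \code{T_lab} (283.15 K, i.e. 10 degC), the dynamic-light-scattering
#' measurement temperature \code{T_dls} (298.15 K, i.e. 25 degC) and the
#' dynamic viscosity of water at 25 degC, \code{eta_dls} (Pa s).
#'
#' @format A named list of scalars.
#' @export
gps_constants <- list(
  # exact CODATA value k_B * N_A; keeping R, k_B and N_A mutually
  # consistent makes the Stokes-Einstein molecular-weight chain cancel
  # exactly against the sphere closed form
  R_gas   = 1.380649e-23 * 6.02214076e23,
  N_A     = 6.02214076e23,
  k_B     = 1.380649e-23,
  T_lab   = 283.15,
  T_dls   = 298.15,
  eta_dls = 8.90e-4,
  earth_radius_m = 6371000
)

# Dynamic viscosity of water (Pa s) against temperature (degC); standard
# handbook values, 0.8900e-3 at 25 degC.  Monotone decreasing.
.eta_water_table <- data.frame(
  temp_C = c(-5, 0, 5, 10, 15, 20, 25, 30, 35, 40),
  eta_Pa_s = c(2.1440, 1.7916, 1.5182, 1.3059, 1.1375,
               1.0016, 0.8900, 0.7972, 0.7190, 0.6527) * 1e-3
)

#' Dynamic viscosity of water
#'
#' Linear interpolation of tabulated handbook values of the dynamic
#' viscosity of pure water, valid between 268.15 K and 313.15 K.
#'
#' @param temperature_K absolute temperature in kelvin (vectorised).
#' @return dynamic viscosity in Pa s.
#' @examples
#' water_viscosity(298.15)  # 8.90e-4 Pa s
#' @export
water_viscosity <- function(temperature_K) {
  if (!is.numeric(temperature_K) || any(!is.finite(temperature_K)))
    stop("temperature must be finite and numeric")
  temp_C <- temperature_K - 273.15
  rng <- range(.eta_water_table$temp_C)
  if (any(temp_C < rng[1] | temp_C > rng[2]))
    stop("temperature outside tabulated viscosity range [",
         rng[1] + 273.15, ", ", rng[2] + 273.15, "] K")
  stats::approx(.eta_water_table$temp_C, .eta_water_table$eta_Pa_s,
                xout = temp_C)$y
}

# Compensated (Kahan) summation; used for grid-wide totals where ~1e4-1e6
# terms of widely varying magnitude are added.
kahan_sum <- function(x) {
  s <- 0
  comp <- 0
  for (xi in x) {
    y <- xi - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}
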