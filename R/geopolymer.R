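#' Stokes-Einstein diffusion coefficient
#'
#' Diffusion coefficient of a spherical particle of hydrodynamic radius
#' \code{r_h} in a medium of viscosity \code{viscosity} at absolute
#' temperature \code{temperature}: D = k_B T / (6 pi eta r_h).
#'
#' @param r_h hydrodynamic radius in metres.
#' @param temperature absolute temperature in K (default: the 25 degC DLS
#'   measurement temperature).
#' @param viscosity dynamic viscosity in Pa s (default: water at
#'   \code{temperature}).
#' @return diffusion coefficient in m^2 s^-1.
#' @examples
#' diffusion_coefficient(3.77e-9)  # ~6.5e-11 m^2 s^-1
#' @export
diffusion_coefficient <- function(r_h, temperature = gps_constants$T_dls,
                                  viscosity = water_viscosity(temperature)) {
  if (any(r_h <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("r_h, temperature and viscosity must be strictly positive")
  gps_constants$k_B * temperature / (6 * pi * viscosity * r_h)
}

#' Molecular weight from a diffusion coefficient
#'
#' Converts a Stokes-Einstein diffusion coefficient into the molecular
#' weight of the diffusing sphere:
#' MW = R^3 T^3 rho / (162 pi^2 N^2 eta^3 D^3).
#' When \code{d_gps} was itself produced by
#' \code{\link{diffusion_coefficient}} at the same temperature and
#' viscosity, the temperature and viscosity cancel and the result equals
#' the sphere mass (4/3) pi r^3 rho N_A.
#'
#' @param d_gps diffusion coefficient, m^2 s^-1.
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity, Pa s.
#' @param rho_gps particle density, kg m^-3 (default 1500, the standard
#'   biomolecule value of 1.5 g cm^-3).
#' @return molecular weight in g mol^-1.
#' @export
molecular_weight <- function(d_gps, temperature = gps_constants$T_dls,
                             viscosity = water_viscosity(temperature),
                             rho_gps = 1500) {
  if (any(d_gps <= 0) || any(temperature <= 0) || any(viscosity <= 0) ||
      any(rho_gps <= 0))
    stop("all inputs must be strictly positive")
  R <- gps_constants$R_gas
  N <- gps_constants$N_A
  mw_kg <- (R^3 * temperature^3 * rho_gps) /
    (162 * pi^2 * N^2 * viscosity^3 * d_gps^3)
  1000 * mw_kg
}

#' Molecular weight of a sphere from its radius
#'
#' Closed-form molar mass of a sphere: (4/3) pi r^3 rho N_A.  Algebraically
#' identical to chaining \code{\link{diffusion_coefficient}} and
#' \code{\link{molecular_weight}} at any common temperature/viscosity pair;
#' used directly when building molecular-weight sampling ranges from
#' dynamic-light-scattering radii.
#'
#' @param r_h radius in metres.
#' @param rho_gps density in kg m^-3.
#' @return molecular weight in g mol^-1.
#' @examples
#' mw_from_radius(3.77e-9)  # ~2.0e5 g mol^-1
#' @export
mw_from_radius <- function(r_h, rho_gps = 1500) {
  if (any(r_h <= 0) || any(rho_gps <= 0))
    stop("r_h and rho_gps must be strictly positive")
  1000 * (4 / 3) * pi * r_h^3 * rho_gps * gps_constants$N_A
}

#' Physical properties of geopolymerized substances
#'
#' Bundles the GPS particle properties used by the upscaling: hydrodynamic
#' radius, Stokes-Einstein diffusion coefficient, molecular weight, density
#' and carbon mass fraction.  The default radius (3.77 nm) is the peak of
#' the dynamic-light-scattering distribution; radii span 3.25-4.36 nm.
#' The default carbon content (0.40 mass fraction) is a placeholder for
#' the elemental-analysis value and should be overridden when a measured
#' value is available.
#'
#' @param r_h_nm hydrodynamic radius in nanometres.
#' @param rho_gps density, kg m^-3.
#' @param c_content carbon mass fraction in (0, 1].
#' @param temperature DLS temperature, K.
#' @param viscosity medium viscosity at \code{temperature}, Pa s.
#' @return object of class \code{gps_properties} with fields \code{r_h}
#'   (m), \code{d_gps} (m^2 s^-1), \code{mw} (g mol^-1), \code{rho_gps},
#'   \code{c_content}, \code{temperature}, \code{viscosity}.
#' @export
gps_properties <- function(r_h_nm = 3.77, rho_gps = 1500, c_content = 0.40,
                           temperature = gps_constants$T_dls,
                           viscosity = gps_constants$eta_dls) {
  if (r_h_nm <= 0 || rho_gps <= 0 || temperature <= 0 || viscosity <= 0)
    stop("radius, density, temperature and viscosity must be positive")
  if (c_content <= 0 || c_content > 1)
    stop("c_content must be a mass fraction in (0, 1]")
  r_h <- r_h_nm * 1e-9
  d <- diffusion_coefficient(r_h, temperature, viscosity)
  mw <- molecular_weight(d, temperature, viscosity, rho_gps)
  structure(list(r_h = r_h, d_gps = d, mw = mw, rho_gps = rho_gps,
                 c_content = c_content, temperature = temperature,
                 viscosity = viscosity),
            class = "gps_properties")
}

#' @export
print.gps_properties <- function(x, digits = 4, ...) {
  cat("GPS particle properties\n")
  cat("  hydrodynamic radius:", signif(x$r_h * 1e9, digits), "nm\n")
  cat("  diffusion coeff:    ", signif(x$d_gps, digits), "m^2 s^-1 (",
      signif(x$temperature, 6), "K )\n")
  cat("  molecular weight:   ", signif(x$mw, digits), "g mol^-1\n")
  cat("  density:            ", x$rho_gps, "kg m^-3\n")
  cat("  carbon content:     ", x$c_content, "(mass fraction)\n")
  invisible(x)
}
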