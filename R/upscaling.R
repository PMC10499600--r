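#' Arrhenius temperature scaling of a laboratory rate
#'
#' Scales the laboratory GPS production rate to the temperature of a grid
#' cell: R = R_lab * exp(-(E_a / R_G) * (1/T - 1/T_lab)).  At T = T_lab
#' the rate equals R_lab exactly, for any activation energy.
#'
#' @param r_lab laboratory rate (any unit; the output keeps it).
#' @param e_a activation energy, J mol^-1 (>= 0).
#' @param temperature cell temperature, K.
#' @param t_lab laboratory incubation temperature, K (283.15).
#' @return scaled rate, same unit as \code{r_lab} (vectorised).
#' @examples
#' arrhenius_rate(1, 1e5, 278.15)  # ~0.466
#' @export
arrhenius_rate <- function(r_lab, e_a, temperature,
                           t_lab = gps_constants$T_lab) {
  if (any(temperature <= 0) || any(t_lab <= 0))
    stop("temperatures must be positive (kelvin)")
  if (any(e_a < 0)) stop("activation energy must be non-negative")
  r_lab * exp(-(e_a / gps_constants$R_gas) * (1 / temperature - 1 / t_lab))
}

#' Parameter set for upscaling laboratory rates to the seafloor
#'
#' Bundles the four physical parameters of the carbon-preservation
#' equation C_pres = MW * C_cont * PV * R_lab * exp(-(E_a/R_G)(1/T -
#' 1/T_lab)).  The rate can be given directly in mol m^-3 yr^-1, in
#' nmol l^-1 yr^-1 via \code{rate_nmol_l_yr}, or as a \code{rate_fit};
#' only mineral-catalysed fits (ferrihydrite, birnessite) are admitted --
#' dissolved-catalyst or control fits require \code{allow_non_mineral =
#' TRUE}, because only the mineral pathway is thought to compete with
#' microbial remineralization in oxic surface sediments.
#'
#' @param rate laboratory rate in mol m^-3 yr^-1, or a \code{rate_fit}.
#' @param e_a activation energy, J mol^-1.
#' @param mw GPS molecular weight, g mol^-1.
#' @param c_content GPS carbon mass fraction in (0, 1].
#' @param rate_nmol_l_yr alternative rate input in nmol l^-1 yr^-1.
#' @param t_lab laboratory temperature, K.
#' @param allow_non_mineral admit a non-mineral \code{rate_fit}?
#' @return object of class \code{upscale_params}.
#' @export
upscale_params <- function(rate = NULL, e_a, mw, c_content,
                           rate_nmol_l_yr = NULL,
                           t_lab = gps_constants$T_lab,
                           allow_non_mineral = FALSE) {
  if (inherits(rate, "rate_fit")) {
    if (!rate$catalyst_kind %in% c("ferrihydrite", "birnessite") &&
        !allow_non_mineral)
      stop("only mineral-catalysed rates (ferrihydrite, birnessite) are ",
           "upscaled by default; set allow_non_mineral = TRUE to override")
    r_lab <- convert_rate(rate$slope, "nmol_l_yr", "mol_m3_yr")
  } else if (!is.null(rate_nmol_l_yr)) {
    r_lab <- convert_rate(rate_nmol_l_yr, "nmol_l_yr", "mol_m3_yr")
  } else if (is.numeric(rate)) {
    r_lab <- rate
  } else stop("supply a rate (mol m^-3 yr^-1), rate_nmol_l_yr, or rate_fit")

  if (!is.finite(r_lab) || r_lab < 0) stop("rate must be finite, >= 0")
  if (!is.finite(e_a) || e_a < 0) stop("e_a must be finite, >= 0")
  if (!is.finite(mw) || mw <= 0) stop("mw must be positive")
  if (!is.finite(c_content) || c_content <= 0 || c_content > 1)
    stop("c_content must be a mass fraction in (0, 1]")
  if (t_lab <= 0) stop("t_lab must be positive")

  structure(list(r_lab = r_lab, e_a = e_a, mw = mw, c_content = c_content,
                 t_lab = t_lab),
            class = "upscale_params")
}

#' @export
print.upscale_params <- function(x, ...) {
  cat("Upscaling parameters\n")
  cat("  R_lab:    ", signif(x$r_lab, 4), "mol m^-3 yr^-1 (",
      signif(convert_rate(x$r_lab, "mol_m3_yr", "nmol_l_yr"), 4),
      "nmol l^-1 yr^-1 )\n")
  cat("  E_a:      ", signif(x$e_a / 1000, 4), "kJ mol^-1\n")
  cat("  MW:       ", signif(x$mw, 4), "g mol^-1\n")
  cat("  C_cont:   ", x$c_content, "(mass fraction)\n")
  cat("  T_lab:    ", x$t_lab, "K\n")
  invisible(x)
}

#' Per-cell carbon preservation rate
#'
#' C_pres = MW * C_cont * PV * R, with R the Arrhenius-scaled rate at the
#' cell temperature.  Zero if and only if the pore-water volume is zero
#' (the rate and parameters being positive).
#'
#' @param params an \code{\link{upscale_params}}.
#' @param pv oxic pore-water volume, m^3 (vectorised).
#' @param temperature cell temperature, K (vectorised).
#' @return carbon preservation rate in g C yr^-1.
#' @export
cell_c_pres <- function(params, pv, temperature) {
  if (!inherits(params, "upscale_params"))
    stop("params must be an upscale_params")
  if (any(!is.finite(pv)) || any(pv < 0))
    stop("pore volume must be finite and non-negative")
  r <- arrhenius_rate(params$r_lab, params$e_a, temperature, params$t_lab)
  params$mw * params$c_content * pv * r
}

#' Global carbon preservation for one parameter set
#'
#' Sums the per-cell carbon preservation over the active cells of a margin
#' grid (compensated summation) and converts to Tg C yr^-1.
#'
#' @param grid a \code{\link{margin_grid}}.
#' @param params an \code{\link{upscale_params}}.
#' @param per_cell also return the per-cell field?
#' @return global rate in Tg C yr^-1; if \code{per_cell = TRUE}, a list
#'   with \code{total_Tg} and the per-cell matrix \code{field_g} (g C
#'   yr^-1, zero on inactive cells).
#' @export
global_c_pres <- function(grid, params, per_cell = FALSE) {
  if (!inherits(grid, "margin_grid")) stop("grid must be a margin_grid")
  if (!any(grid$active)) {
    warning("no active cells; global preservation is zero")
    if (per_cell)
      return(list(total_Tg = 0,
                  field_g = matrix(0, length(grid$lat), length(grid$lon))))
    return(0)
  }
  act <- grid$active
  cp <- cell_c_pres(params, grid$pore_volume[act], grid$temperature[act])
  total <- kahan_sum(cp) / 1e12
  if (!per_cell) return(total)
  field <- matrix(0, length(grid$lat), length(grid$lon))
  field[act] <- cp
  list(total_Tg = total, field_g = field)
}
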