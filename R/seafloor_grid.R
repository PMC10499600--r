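#' Oxygen-penetration-depth relation
#'
#' Empirical power-law relation between water depth and oxygen penetration
#' depth (OPD) in the sediment: log10(Z_O2 in cm) = a + b * log10(depth in
#' m).  Depths below \code{depth_floor} are floored before taking the log,
#' and the evaluated OPD is optionally clamped to the
#' \code{[opd_min_cm, opd_max_cm]} envelope so extreme bathymetry cannot
#' push the oxic-layer thickness outside the calibrated span.
#'
#' @param a,b intercept and slope in log10-log10 space (cm against m).
#' @param depth_floor minimum depth (m) substituted before the log.
#' @param opd_min_cm,opd_max_cm clamping envelope, cm.
#' @param clamp logical; clamp the evaluated OPD to the envelope?
#' @return object of class \code{opd_relation}.
#' @seealso \code{\link{calibrate_opd}}, \code{\link{opd_from_depth}}
#' @export
opd_relation <- function(a, b, depth_floor = 10,
                         opd_min_cm = 0.56, opd_max_cm = 1.10,
                         clamp = TRUE) {
  if (!is.finite(a) || !is.finite(b)) stop("coefficients must be finite")
  if (depth_floor <= 0) stop("depth_floor must be positive")
  if (opd_min_cm <= 0 || opd_max_cm < opd_min_cm)
    stop("invalid clamping envelope")
  structure(list(a = a, b = b, depth_floor = depth_floor,
                 opd_min_cm = opd_min_cm, opd_max_cm = opd_max_cm,
                 clamp = clamp),
            class = "opd_relation")
}

#' @export
print.opd_relation <- function(x, ...) {
  cat("OPD relation: log10(Z_O2 / cm) =", signif(x$a, 5), "+",
      signif(x$b, 5), "* log10(depth / m)\n")
  cat("  depth floor:", x$depth_floor, "m;",
      if (x$clamp) paste0("clamped to [", x$opd_min_cm, ", ",
                          x$opd_max_cm, "] cm") else "unclamped", "\n")
  invisible(x)
}

#' Calibrate the OPD-depth relation from anchor points
#'
#' Least-squares fit of the log-log power law through anchor
#' (depth, OPD) pairs; with exactly two distinct anchors the fit is exact.
#' The default anchors reproduce the calibrated OPD envelope: 0.56 cm at
#' 10 m and 1.10 cm at 1000 m water depth.
#'
#' @param depth_m anchor water depths, m.
#' @param opd_cm anchor oxygen penetration depths, cm.
#' @param ... passed to \code{\link{opd_relation}} (clamping, floor).
#' @return an \code{opd_relation}.
#' @export
calibrate_opd <- function(depth_m = c(10, 1000), opd_cm = c(0.56, 1.10),
                          ...) {
  if (length(depth_m) != length(opd_cm))
    stop("depth_m and opd_cm must have equal length")
  if (length(unique(depth_m)) < 2)
    stop("degenerate calibration: need at least 2 distinct depths")
  if (any(depth_m <= 0) || any(opd_cm <= 0))
    stop("anchors must be strictly positive")
  fit <- stats::lm(log10(opd_cm) ~ log10(depth_m))
  cf <- unname(stats::coef(fit))
  opd_relation(a = cf[1], b = cf[2],
               opd_min_cm = min(opd_cm), opd_max_cm = max(opd_cm), ...)
}

#' Default OPD-depth relation
#'
#' The two-anchor calibration through (10 m, 0.56 cm) and
#' (1000 m, 1.10 cm), clamped to that envelope.
#'
#' @return an \code{\link{opd_relation}}.
#' @export
default_opd_relation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_opd()
    cache
  }
})

#' Oxygen penetration depth from water depth
#'
#' Evaluates an \code{\link{opd_relation}} at the given water depths.
#'
#' @param depth water depth in metres, positive downward.
#' @param relation an \code{opd_relation}; defaults to the two-anchor
#'   calibration against the 0.56-1.10 cm envelope.
#' @return oxygen penetration depth in metres.
#' @examples
#' opd_from_depth(c(10, 100, 1000)) * 100  # cm
#' @export
opd_from_depth <- function(depth, relation = default_opd_relation()) {
  if (!inherits(relation, "opd_relation"))
    stop("relation must be an opd_relation")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("depth must be positive and finite")
  d <- pmax(depth, relation$depth_floor)
  z_cm <- 10^(relation$a + relation$b * log10(d))
  if (relation$clamp)
    z_cm <- pmin(pmax(z_cm, relation$opd_min_cm), relation$opd_max_cm)
  z_cm / 100
}

#' Spherical-Earth area of a latitude-longitude cell
#'
#' Area of the cell bounded by two parallels and two meridians on a sphere
#' of radius \code{radius}: R^2 * dlambda * (sin(lat_n) - sin(lat_s)).
#'
#' @param lat_south,lat_north latitude bounds in degrees, south < north.
#' @param lon_west,lon_east longitude bounds in degrees (span <= 360).
#' @param radius Earth radius in metres.
#' @return area in m^2 (vectorised over cell bounds).
#' @examples
#' cell_area(-90, 90, -180, 180)  # full sphere, ~5.1e14 m^2
#' @export
cell_area <- function(lat_south, lat_north, lon_west, lon_east,
                      radius = gps_constants$earth_radius_m) {
  if (any(lat_south < -90) || any(lat_north > 90))
    stop("latitude bounds must lie in [-90, 90]")
  if (any(lat_south >= lat_north))
    stop("inverted latitude bounds: require south < north")
  dlon <- lon_east - lon_west
  if (any(dlon <= 0) || any(dlon > 360))
    stop("longitude span must be in (0, 360] degrees")
  rad <- pi / 180
  radius^2 * (dlon * rad) * (sin(lat_north * rad) - sin(lat_south * rad))
}

#' Oxic-layer pore-water volume
#'
#' PV = phi * Z_O2 * S: porosity times oxygen penetration depth times
#' sediment surface area.  Porosity is treated as depth-constant within
#' the oxic layer (compaction acts over tens of metres, not the
#' centimetre-scale OPD, and is deliberately ignored).
#'
#' @param phi porosity, dimensionless in [0, 1].
#' @param z_o2 oxygen penetration depth, m.
#' @param area sediment surface area, m^2.
#' @return pore-water volume in m^3.
#' @export
pore_volume <- function(phi, z_o2, area) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("porosity must be finite and in [0, 1]")
  if (any(!is.finite(z_o2)) || any(z_o2 < 0))
    stop("z_o2 must be finite and non-negative")
  if (any(!is.finite(area)) || any(area < 0))
    stop("area must be finite and non-negative")
  phi * z_o2 * area
}

#' Continental-margin grid
#'
#' Regular latitude-longitude grid (cell-centre registration; cells are
#' half-open [south, north) x [west, east)) holding the per-cell fields
#' the upscaling needs: water depth, porosity, bottom-water temperature,
#' cell area, oxygen penetration depth and oxic pore-water volume.  A cell
#' is \emph{active} -- i.e. part of the continental margin considered by
#' the analysis -- when its depth lies in (0, \code{max_depth_m}] m (shelf
#' 0-200 m plus upper slope 200-1000 m) and all its fields are finite.
#' Inactive cells contribute nothing downstream.
#'
#' @param lat,lon cell-centre coordinates, degrees; must be equally
#'   spaced and ascending.
#' @param depth n_lat x n_lon matrix of water depth, m, positive downward
#'   (non-positive = land).
#' @param porosity matrix of porosity in [0, 1].
#' @param temperature matrix of bottom-water temperature, K.
#' @param relation OPD-depth relation used to fill the oxygen penetration
#'   depth.
#' @param max_depth_m deepest water depth counted as margin (default
#'   1000 m).
#' @param area optional matrix of cell areas, m^2; computed from the grid
#'   geometry when omitted.
#' @return object of class \code{margin_grid}.
#' @export
margin_grid <- function(lat, lon, depth, porosity, temperature,
                        relation = default_opd_relation(),
                        max_depth_m = 1000, area = NULL) {
  n_lat <- length(lat); n_lon <- length(lon)
  if (n_lat < 1 || n_lon < 1) stop("empty grid")
  regular <- function(x) {
    d <- diff(x)
    length(d) == 0 ||
      (all(d > 0) && max(abs(d - mean(d))) <= 1e-8 * abs(mean(d)))
  }
  if (!regular(lat)) stop("lat must be ascending and equally spaced")
  if (!regular(lon)) stop("lon must be ascending and equally spaced")
  chk <- function(m, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(n_lat, n_lon)))
      stop(nm, " must be an n_lat x n_lon matrix")
    m
  }
  depth <- chk(depth, "depth")
  porosity <- chk(porosity, "porosity")
  temperature <- chk(temperature, "temperature")
  if (any(is.finite(porosity) & (porosity < 0 | porosity > 1)))
    stop("porosity must lie in [0, 1]")
  if (any(is.finite(temperature) & temperature <= 0))
    stop("temperature must be positive (kelvin)")

  dlat <- if (n_lat > 1) mean(diff(lat)) else 0.25
  dlon <- if (n_lon > 1) mean(diff(lon)) else 0.25
  if (is.null(area)) {
    band <- cell_area(lat - dlat / 2, lat + dlat / 2, 0, dlon)
    area <- matrix(band, n_lat, n_lon)
  } else {
    area <- chk(area, "area")
    if (any(is.finite(area) & area <= 0)) stop("area must be positive")
  }

  active <- is.finite(depth) & depth > 0 & depth <= max_depth_m &
    is.finite(porosity) & is.finite(temperature) & is.finite(area)
  opd <- matrix(NA_real_, n_lat, n_lon)
  pv <- matrix(0, n_lat, n_lon)
  if (any(active)) {
    opd[active] <- opd_from_depth(depth[active], relation)
    pv[active] <- pore_volume(porosity[active], opd[active], area[active])
  }

  structure(list(lat = lat, lon = lon, dlat = dlat, dlon = dlon,
                 depth = depth, porosity = porosity,
                 temperature = temperature, area = area,
                 opd = opd, pore_volume = pv, active = active,
                 max_depth_m = max_depth_m, relation = relation),
            class = "margin_grid")
}

#' @export
print.margin_grid <- function(x, ...) {
  n_act <- sum(x$active)
  cat("Continental-margin grid:", length(x$lat), "x", length(x$lon),
      "cells (", signif(x$dlat, 3), "deg x", signif(x$dlon, 3), "deg )\n")
  cat("  active margin cells:", n_act,
      sprintf("(%.1f%%)", 100 * n_act / length(x$active)), "\n")
  if (n_act > 0) {
    cat("  active depth range: ",
        paste(signif(range(x$depth[x$active]), 4), collapse = " - "), "m\n")
    cat("  active area:        ",
        signif(sum(x$area[x$active]), 4), "m^2\n")
    cat("  total pore volume:  ",
        signif(total_pore_volume(x), 4), "m^3 (",
        signif(total_pore_volume(x, unit = "l"), 4), "l )\n")
  }
  invisible(x)
}

#' @export
plot.margin_grid <- function(x, field = c("depth", "pore_volume", "porosity",
                                          "temperature", "opd"), ...) {
  field <- match.arg(field)
  z <- x[[field]]
  z[!x$active] <- NA
  graphics::image(x$lon, x$lat, t(z), xlab = "longitude", ylab = "latitude",
                  main = paste("active-margin", field), ...)
  invisible(x)
}

#' Total reactive pore-water volume of a margin grid
#'
#' Compensated sum of the oxic pore-water volume over active cells only.
#'
#' @param grid a \code{\link{margin_grid}}.
#' @param unit \code{"m3"} (default) or \code{"l"}.
#' @return total volume (scalar).
#' @export
total_pore_volume <- function(grid, unit = c("m3", "l")) {
  unit <- match.arg(unit)
  if (!inherits(grid, "margin_grid")) stop("grid must be a margin_grid")
  if (!any(grid$active)) {
    warning("no active cells; total pore volume is zero")
    return(0)
  }
  v <- kahan_sum(grid$pore_volume[grid$active])
  if (unit == "l") v * 1000 else v
}

#' Rescale cell areas to a target active-margin area
#'
#' Multiplies every cell area by a common factor so the summed area of
#' active cells equals \code{total_active_area_m2} (for example the
#' real-world continental shelf + upper slope area), and recomputes the
#' pore-water volumes.  Used to place synthetic grids on a realistic
#' areal footing.
#'
#' @param grid a \code{\link{margin_grid}}.
#' @param total_active_area_m2 target summed active area, m^2.
#' @return rescaled \code{margin_grid}.
#' @export
rescale_area <- function(grid, total_active_area_m2) {
  if (!inherits(grid, "margin_grid")) stop("grid must be a margin_grid")
  if (!is.finite(total_active_area_m2) || total_active_area_m2 <= 0)
    stop("target area must be positive")
  cur <- sum(grid$area[grid$active])
  if (cur <= 0) stop("grid has no active area to rescale")
  f <- total_active_area_m2 / cur
  grid$area <- grid$area * f
  grid$pore_volume <- grid$pore_volume * f
  grid
}
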