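#' Simulate an Earth-like continental-margin grid
#'
#' Generates a regular lat-lon grid whose active cells emulate the
#' continental margin: a depth mixture spanning the shelf (0-200 m) and
#' upper slope (200-1000 m), porosity drawn from a truncated normal, and
#' bottom-water temperature decreasing with depth and latitude,
#' T(degC) = t0 - k_depth*log10(depth) - k_lat*|lat|/90 + noise, truncated
#' to \code{temp_range_C}.  Inactive cells are split between land and
#' deep sea so downstream masking is exercised.  The generator is fully
#' reproducible from its seed and leaves the global RNG state untouched.
#'
#' @param n_lat,n_lon grid shape (default 90 x 180).
#' @param lat_range,lon_range extent of cell centres, degrees.
#' @param active_fraction fraction of cells that are margin (default
#'   0.10).
#' @param shelf_fraction fraction of active cells with shelf depths
#'   (default 0.6, roughly the real shelf share of the 0-1000 m margin).
#' @param shelf_depth_range,slope_depth_range depth supports, m.
#' @param porosity_mean,porosity_sd porosity distribution (clipped to
#'   [0, 1]).
#' @param t0_C,k_depth_C,k_lat_C,temp_noise_sd_C temperature-model
#'   coefficients, degC.
#' @param temp_range_C truncation range for temperature, degC.
#' @param total_active_area_m2 optional target for the summed active-cell
#'   area (e.g. 3e13 m^2, the approximate real shelf + upper-slope area);
#'   when given, areas are rescaled via \code{\link{rescale_area}}.
#' @param relation OPD-depth relation.
#' @param seed integer seed.
#' @return a \code{\link{margin_grid}}.
#' @export
simulate_margin_grid <- function(n_lat = 90, n_lon = 180,
                                 lat_range = c(-70, 70),
                                 lon_range = c(-180, 180),
                                 active_fraction = 0.10,
                                 shelf_fraction = 0.6,
                                 shelf_depth_range = c(5, 200),
                                 slope_depth_range = c(200, 1000),
                                 porosity_mean = 0.7, porosity_sd = 0.08,
                                 t0_C = 15, k_depth_C = 3, k_lat_C = 12,
                                 temp_noise_sd_C = 1,
                                 temp_range_C = c(-2, 30),
                                 total_active_area_m2 = NULL,
                                 relation = default_opd_relation(),
                                 seed = 1) {
  if (n_lat < 1 || n_lon < 1) stop("grid shape must be positive")
  if (active_fraction < 0 || active_fraction > 1 ||
      shelf_fraction < 0 || shelf_fraction > 1)
    stop("fractions must lie in [0, 1]")
  dlat <- diff(lat_range) / n_lat
  dlon <- diff(lon_range) / n_lon
  lat <- lat_range[1] + (seq_len(n_lat) - 0.5) * dlat
  lon <- lon_range[1] + (seq_len(n_lon) - 0.5) * dlon
  n <- n_lat * n_lon

  grid <- with_preserved_rng({
    set.seed(as.integer(seed))
    n_active <- round(active_fraction * n)
    idx <- sample.int(n, n_active)
    is_shelf <- stats::runif(n_active) < shelf_fraction

    depth <- rep(NA_real_, n)
    inactive <- setdiff(seq_len(n), idx)
    # half land, half deep ocean among inactive cells
    land <- inactive[seq_len(floor(length(inactive) / 2))]
    depth[land] <- -50
    depth[setdiff(inactive, land)] <- 2500
    depth[idx[is_shelf]] <- stats::runif(sum(is_shelf),
                                         shelf_depth_range[1],
                                         shelf_depth_range[2])
    depth[idx[!is_shelf]] <- stats::runif(sum(!is_shelf),
                                          slope_depth_range[1],
                                          slope_depth_range[2])
    depth <- matrix(depth, n_lat, n_lon)

    porosity <- matrix(pmin(pmax(stats::rnorm(n, porosity_mean,
                                              porosity_sd), 0), 1),
                       n_lat, n_lon)
    lat_m <- matrix(lat, n_lat, n_lon)
    t_C <- t0_C - k_depth_C * log10(pmax(abs(depth), 1)) -
      k_lat_C * abs(lat_m) / 90 +
      matrix(stats::rnorm(n, 0, temp_noise_sd_C), n_lat, n_lon)
    t_C <- pmin(pmax(t_C, temp_range_C[1]), temp_range_C[2])

    margin_grid(lat, lon, depth, porosity, t_C + 273.15,
                relation = relation)
  })
  if (!is.null(total_active_area_m2))
    grid <- rescale_area(grid, total_active_area_m2)
  grid
}

#' Simulate an incubation time series
#'
#' Linear-in-time GPS production with additive Gaussian noise, floored at
#' zero (concentrations cannot be negative):
#' gps = intercept + true_slope * time_years + N(0, noise_sd).
#'
#' @param true_slope true production rate, nmol l^-1 yr^-1.
#' @param intercept initial GPS concentration, nmol l^-1.
#' @param n_timepoints number of sampling times (>= 2).
#' @param dt_days sampling interval in days (aliquots taken daily by
#'   default).
#' @param noise_sd Gaussian noise SD, nmol l^-1.
#' @param n_replicates number of replicate bottles.
#' @param seed integer seed.
#' @param condition_label,catalyst_kind,catalyst_amount,catalyst_unit
#'   condition metadata passed to \code{\link{incubation_series}}.
#' @return an \code{\link{incubation_series}}.
#' @export
simulate_incubation <- function(true_slope, intercept = 0,
                                n_timepoints = 10, dt_days = 1,
                                noise_sd = 0.005, n_replicates = 3,
                                seed = 1,
                                condition_label = "synthetic",
                                catalyst_kind = "birnessite",
                                catalyst_amount = 2.5,
                                catalyst_unit = "g_l") {
  if (n_timepoints < 2) stop("need at least 2 time points")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("need at least 1 replicate")
  t_years <- (seq_len(n_timepoints) - 1) * dt_days / 365.25
  d <- with_preserved_rng({
    set.seed(as.integer(seed))
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      gps <- intercept + true_slope * t_years +
        stats::rnorm(n_timepoints, 0, noise_sd)
      data.frame(replicate_id = r, time_years = t_years,
                 gps_nmol_per_l = pmax(gps, 0))
    }))
  })
  incubation_series(d, condition_label = condition_label,
                    catalyst_kind = catalyst_kind,
                    catalyst_amount = catalyst_amount,
                    catalyst_unit = catalyst_unit)
}

#' Simulate the published incubation conditions
#'
#' One synthetic incubation series per published condition (control,
#' dissolved Fe/Mn at 400 umol l^-1, ferrihydrite/birnessite at
#' 2.5 g l^-1; see \code{\link{reported_rates}}), with the published rate
#' as the true slope.  The noise SD of each condition is chosen so the
#' pooled-regression standard error matches the published standard error
#' of that rate (sigma = SE * sqrt(sum((t - mean(t))^2))), and a small
#' baseline offset of three noise SDs keeps the zero floor from censoring
#' early time points.
#'
#' @param seed integer seed.
#' @param n_timepoints,dt_days,n_replicates sampling design (default: 10
#'   daily aliquots, 3 replicates).
#' @return named list of \code{\link{incubation_series}}.
#' @export
simulate_reported_incubations <- function(seed = 1, n_timepoints = 10,
                                          dt_days = 1, n_replicates = 3) {
  tbl <- reported_rates()
  t_years <- (seq_len(n_timepoints) - 1) * dt_days / 365.25
  sxx <- sqrt(n_replicates * sum((t_years - mean(t_years))^2))
  out <- lapply(seq_len(nrow(tbl)), function(i) {
    noise <- tbl$se_nmol_l_yr[i] * sxx
    simulate_incubation(true_slope = tbl$rate_nmol_l_yr[i],
                        intercept = 3 * noise,
                        n_timepoints = n_timepoints, dt_days = dt_days,
                        noise_sd = noise, n_replicates = n_replicates,
                        seed = seed + i,
                        condition_label = tbl$condition_label[i],
                        catalyst_kind = tbl$catalyst_kind[i],
                        catalyst_amount = tbl$catalyst_amount[i],
                        catalyst_unit = tbl$catalyst_unit[i])
  })
  names(out) <- tbl$condition_label
  out
}

#' Simulate dynamic-light-scattering radius samples
#'
#' Draws hydrodynamic radii from a triangular distribution -- the minimal
#' distribution matching the reported support and peak of the DLS
#' intensity distribution (3.25-4.36 nm, peak 3.77 nm).
#'
#' @param n number of draws.
#' @param lo_nm,peak_nm,hi_nm support bounds and mode, nm
#'   (lo < peak < hi).
#' @param seed integer seed.
#' @return numeric vector of radii in nm.
#' @export
simulate_dls_radii <- function(n, lo_nm = 3.25, peak_nm = 3.77,
                               hi_nm = 4.36, seed = 1) {
  if (!(lo_nm < peak_nm && peak_nm < hi_nm))
    stop("require lo_nm < peak_nm < hi_nm")
  if (n < 1) stop("n must be >= 1")
  with_preserved_rng({
    set.seed(as.integer(seed))
    u <- stats::runif(n)
    fc <- (peak_nm - lo_nm) / (hi_nm - lo_nm)
    ifelse(u < fc,
           lo_nm + sqrt(u * (hi_nm - lo_nm) * (peak_nm - lo_nm)),
           hi_nm - sqrt((1 - u) * (hi_nm - lo_nm) * (hi_nm - peak_nm)))
  })
}
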