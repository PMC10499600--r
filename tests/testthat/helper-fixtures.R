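# Shared fixtures and independent oracles, built in code at test time.

# Margin grid with constant fields on a regular lat-lon patch; every cell
# active unless depth says otherwise.
make_uniform_grid <- function(n_lat = 5, n_lon = 5, depth = 100, phi = 0.7,
                              temp_K = 278.15, lat_range = c(0, 10),
                              lon_range = c(0, 10), ...) {
  dlat <- diff(lat_range) / n_lat
  dlon <- diff(lon_range) / n_lon
  lat <- lat_range[1] + (seq_len(n_lat) - 0.5) * dlat
  lon <- lon_range[1] + (seq_len(n_lon) - 0.5) * dlon
  m <- function(v) matrix(v, n_lat, n_lon)
  margin_grid(lat, lon, m(depth), m(phi), m(temp_K), ...)
}

# Independent expectation of the shared-draws Monte Carlo global mean:
# product of uniform means for the multiplicative parameters, and 1-D
# numeric quadrature of the Arrhenius factor over the activation-energy
# range, cell by cell.
mc_oracle_mean_tg <- function(grid, ranges, t_lab = gps_constants$T_lab) {
  act <- grid$active
  pv <- grid$pore_volume[act]
  cf <- -(1 / grid$temperature[act] - 1 / t_lab) / gps_constants$R_gas
  umean <- function(r) (r$lo + r$hi) / 2
  ea <- ranges$activation_energy
  eterm <- vapply(cf, function(ci) {
    stats::integrate(function(e) exp(ci * e), ea$lo, ea$hi,
                     rel.tol = 1e-12)$value / (ea$hi - ea$lo)
  }, numeric(1))
  umean(ranges$molecular_weight) * umean(ranges$c_content) *
    umean(ranges$rate) * 1e-6 * sum(pv * eterm) / 1e12
}

# Closed-form OLS slope and its standard error (textbook formulas),
# independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       stderr = sqrt(sigma2 / sxx))
}
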