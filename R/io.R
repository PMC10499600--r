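#' Read incubation tables from CSV
#'
#' Expects columns \code{condition_label}, \code{catalyst_kind},
#' \code{catalyst_amount}, \code{catalyst_unit}, \code{replicate_id},
#' \code{time_years} (or \code{time_days}) and \code{gps_nmol_per_l};
#' rows are grouped by condition.
#'
#' @param path CSV file path.
#' @return named list of \code{\link{incubation_series}}, one per
#'   condition.
#' @export
read_incubation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty incubation table: ", path)
  need <- c("condition_label", "catalyst_kind", "catalyst_amount",
            "catalyst_unit", "replicate_id", "gps_nmol_per_l")
  miss <- setdiff(need, names(d))
  if (!any(c("time_years", "time_days") %in% names(d)))
    miss <- c(miss, "time_years")
  if (length(miss))
    stop("incubation table missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(d, d$condition_label), function(g) {
    incubation_series(g, condition_label = g$condition_label[1],
                      catalyst_kind = g$catalyst_kind[1],
                      catalyst_amount = g$catalyst_amount[1],
                      catalyst_unit = g$catalyst_unit[1])
  })
  out[unique(d$condition_label)]
}

#' Write incubation series to CSV
#'
#' @param series an \code{\link{incubation_series}} or a list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_incubation_csv <- function(series, path) {
  if (inherits(series, "incubation_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(condition_label = s$condition_label,
               catalyst_kind = s$catalyst_kind,
               catalyst_amount = s$catalyst_amount,
               catalyst_unit = s$catalyst_unit,
               replicate_id = s$data$replicate_id,
               time_years = s$data$time_years,
               gps_nmol_per_l = s$data$gps_nmol_per_l,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit rates for every condition in a list of series
#'
#' @param series_list list of \code{\link{incubation_series}}.
#' @return data.frame with one row per condition: metadata plus slope,
#'   stderr, r_squared, n_obs and intercept.
#' @export
fit_rates_table <- function(series_list) {
  if (inherits(series_list, "incubation_series"))
    series_list <- list(series_list)
  do.call(rbind, lapply(series_list, function(s) {
    f <- fit_rate(s)
    data.frame(condition_label = f$condition_label,
               catalyst_kind = f$catalyst_kind,
               catalyst_amount = f$catalyst_amount,
               catalyst_unit = f$catalyst_unit,
               slope_nmol_l_yr = f$slope, stderr_nmol_l_yr = f$stderr,
               r_squared = f$r_squared, n_obs = f$n_obs,
               intercept_nmol_l = f$intercept,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

# -- gridded field I/O ------------------------------------------------------
# Plain-text gridded format: a `#key: value` attribute header (units,
# registration, grid shape) followed by a long-format CSV table of cell
# centres.  Self-describing, diff-able and byte-deterministic.

grid_header <- function(grid, fields) {
  c("#maillard_grid: 1",
    "#registration: cell_centre, cells half-open [south,north) x [west,east)",
    paste0("#n_lat: ", length(grid$lat)),
    paste0("#n_lon: ", length(grid$lon)),
    paste0("#cell_size_deg: ", format(grid$dlat, digits = 10), " ",
           format(grid$dlon, digits = 10)),
    paste0("#max_depth_m: ", format(grid$max_depth_m, digits = 10)),
    paste0("#units: lat=degrees_north lon=degrees_east ",
           paste(fields, collapse = " ")))
}

#' Write a margin grid to a self-describing CSV file
#'
#' Writes the primary fields (depth, porosity, temperature, cell area) as
#' a long-format CSV preceded by a \code{#key: value} attribute header
#' recording units, grid registration and shape.  Derived fields (OPD,
#' pore volume, mask) are recomputed on read.
#'
#' @param grid a \code{\link{margin_grid}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_margin_grid <- function(grid, path) {
  if (!inherits(grid, "margin_grid")) stop("grid must be a margin_grid")
  hdr <- grid_header(grid, c("depth_m=m", "porosity=1",
                             "bottom_water_temp_K=K", "area_m2=m2"))
  idx <- expand.grid(ilat = seq_along(grid$lat), ilon = seq_along(grid$lon))
  d <- data.frame(lat = grid$lat[idx$ilat], lon = grid$lon[idx$ilon],
                  depth_m = grid$depth[as.matrix(idx)],
                  porosity = grid$porosity[as.matrix(idx)],
                  bottom_water_temp_K = grid$temperature[as.matrix(idx)],
                  area_m2 = grid$area[as.matrix(idx)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a margin grid written by \code{write_margin_grid}
#'
#' @param path file path.
#' @param relation OPD relation used to recompute the derived fields.
#' @return a \code{\link{margin_grid}}.
#' @export
read_margin_grid <- function(path, relation = default_opd_relation()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  if (!any(grepl("^#maillard_grid:", hdr)))
    stop("not a maillard grid file (missing #maillard_grid header): ", path)
  get_attr <- function(key) {
    ln <- hdr[grepl(paste0("^#", key, ":"), hdr)]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^#", key, ":"), "", ln[1]))
  }
  max_depth <- as.numeric(get_attr("max_depth_m"))
  d <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"))
  need <- c("lat", "lon", "depth_m", "porosity", "bottom_water_temp_K",
            "area_m2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("grid file missing column(s): ", paste(miss, collapse = ", "))
  lat <- sort(unique(d$lat))
  lon <- sort(unique(d$lon))
  ilat <- match(d$lat, lat)
  ilon <- match(d$lon, lon)
  put <- function(v) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(ilat, ilon)] <- v
    m
  }
  margin_grid(lat, lon, put(d$depth_m), put(d$porosity),
              put(d$bottom_water_temp_K), relation = relation,
              max_depth_m = if (length(max_depth)) max_depth else 1000,
              area = put(d$area_m2))
}

#' Write a per-cell field alongside its grid coordinates
#'
#' @param grid the \code{\link{margin_grid}} the field lives on.
#' @param field n_lat x n_lon numeric matrix.
#' @param name column name for the field (units in the name).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_field_csv <- function(grid, field, name, path) {
  if (!all(dim(field) == c(length(grid$lat), length(grid$lon))))
    stop("field dimensions do not match the grid")
  hdr <- grid_header(grid, paste0(name, "=see_name"))
  idx <- expand.grid(ilat = seq_along(grid$lat), ilon = seq_along(grid$lon))
  d <- data.frame(lat = grid$lat[idx$ilat], lon = grid$lon[idx$ilon],
                  value = field[as.matrix(idx)])
  names(d)[3] <- name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Serialises a run's resolved configuration and results so any output can
#' be reproduced from its report.  Content is deterministic: no
#' timestamps go into the file (wall-clock is logged to the console
#' instead).
#'
#' @param report named list.
#' @param path output path (.json).
#' @return \code{path}, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

range_to_list <- function(r) {
  list(name = r$name, raw_min = r$raw_min, raw_max = r$raw_max,
       sd_used = r$sd_used, lo = r$lo, hi = r$hi,
       provenance = r$provenance)
}
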