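test_that("two-anchor OPD calibration is exact and matches hand log arithmetic", {
  rel <- calibrate_opd(c(10, 1000), c(0.56, 1.10))
  expect_equal(rel$b, 0.146602329076, tolerance = 1e-9)
  expect_equal(opd_from_depth(10, rel) * 100, 0.56, tolerance = 1e-9)
  expect_equal(opd_from_depth(1000, rel) * 100, 1.10, tolerance = 1e-9)
  # hand evaluation of the power law at 100 m
  expect_equal(opd_from_depth(100, rel) * 100, 0.784856674814,
               tolerance = 1e-9)
})

test_that("calibration through points on a perfect power law has zero residuals", {
  d <- c(20, 50, 200, 800)
  z <- 10^(-0.4 + 0.15 * log10(d))
  rel <- calibrate_opd(d, z, clamp = FALSE)
  expect_equal(rel$a, -0.4, tolerance = 1e-10)
  expect_equal(rel$b, 0.15, tolerance = 1e-10)
  expect_equal(opd_from_depth(d, rel) * 100, z, tolerance = 1e-10)
  expect_error(calibrate_opd(c(10, 10), c(1, 2)), "degenerate")
})

test_that("OPD is monotone, floored in depth, clamped to the calibrated envelope", {
  depths <- seq(1, 1000, by = 1)
  z_cm <- opd_from_depth(depths) * 100
  expect_true(all(diff(z_cm) >= 0))
  expect_true(all(z_cm >= 0.56 - 1e-12 & z_cm <= 1.10 + 1e-12))
  # below the 10 m floor the OPD is constant
  expect_equal(opd_from_depth(1), opd_from_depth(10))
  # degenerate slope: constant OPD everywhere
  flat <- opd_relation(a = log10(0.8), b = 0, clamp = FALSE)
  expect_equal(opd_from_depth(c(15, 150, 900), flat) * 100, rep(0.8, 3))
  expect_error(opd_from_depth(-5), "positive")
  expect_error(opd_from_depth(0), "positive")
})

test_that("cell areas reproduce closed forms and spherical symmetry", {
  expect_equal(cell_area(-90, 90, -180, 180), 4 * pi * 6371000^2,
               tolerance = 1e-12)
  expect_equal(cell_area(0, 0.25, 0, 0.25), 772767029.897, tolerance = 1e-9)
  expect_equal(cell_area(-30, -20, 10, 20), cell_area(20, 30, 10, 20),
               tolerance = 1e-12)
  expect_error(cell_area(10, 5, 0, 1), "inverted")
  expect_error(cell_area(-100, 5, 0, 1), "latitude")
})

test_that("summed cell areas match the closed-form band area", {
  lat_s <- seq(10, 19.75, by = 0.25)
  lon_w <- seq(0, 359.75, by = 0.25)
  cells <- outer(seq_along(lat_s), seq_along(lon_w),
                 function(i, j) cell_area(lat_s[i], lat_s[i] + 0.25,
                                          lon_w[j], lon_w[j] + 0.25))
  band <- cell_area(10, 20, 0, 360)
  expect_equal(sum(cells), band, tolerance = 1e-10)
})

test_that("pore volume is the product of porosity, OPD and area", {
  expect_equal(pore_volume(0, 1, 1e6), 0)
  expect_equal(pore_volume(1, 1, 1), 1)
  expect_equal(pore_volume(0.7, 0.0066, 1e6), 4620)
  expect_error(pore_volume(1.2, 1, 1), "porosity")
  expect_error(pore_volume(0.5, -1, 1), "z_o2")
})

test_that("margin grid masks land and deep cells out of all totals", {
  depth <- matrix(c(-10, 100, 500, 1500), 2, 2)  # land, shelf, slope, deep
  g <- margin_grid(lat = c(0.5, 1.5), lon = c(0.5, 1.5), depth,
                   porosity = matrix(0.7, 2, 2),
                   temperature = matrix(278, 2, 2))
  expect_equal(sum(g$active), 2)
  expect_false(g$active[1, 1])  # land
  expect_false(g$active[2, 2])  # > 1000 m
  expect_equal(g$pore_volume[1, 1], 0)
  expect_equal(total_pore_volume(g),
               sum(g$pore_volume[g$active]), tolerance = 1e-12)
  # single-active-cell grid: total equals that cell's PV
  g1 <- margin_grid(1, 1, matrix(100), matrix(0.7), matrix(278))
  expect_equal(total_pore_volume(g1), g1$pore_volume[1, 1])
  expect_equal(total_pore_volume(g1, unit = "l"),
               1000 * g1$pore_volume[1, 1])
})

test_that("total pore volume is additive over disjoint grids", {
  g1 <- make_uniform_grid(3, 3, depth = 80, lat_range = c(0, 3),
                          lon_range = c(0, 3))
  g2 <- make_uniform_grid(3, 3, depth = 400, lat_range = c(3, 6),
                          lon_range = c(0, 3))
  big <- margin_grid(c(g1$lat, g2$lat), g1$lon,
                     rbind(g1$depth, g2$depth),
                     rbind(g1$porosity, g2$porosity),
                     rbind(g1$temperature, g2$temperature))
  expect_equal(total_pore_volume(big),
               total_pore_volume(g1) + total_pore_volume(g2),
               tolerance = 1e-9)
})

test_that("empty active set warns and returns zero", {
  g <- margin_grid(1, 1, matrix(-5), matrix(0.5), matrix(280))
  expect_warning(v <- total_pore_volume(g), "no active cells")
  expect_equal(v, 0)
})

test_that("rescale_area hits the target active area and scales PV with it", {
  g <- make_uniform_grid(4, 4)
  g2 <- rescale_area(g, 3e13)
  expect_equal(sum(g2$area[g2$active]), 3e13, tolerance = 1e-12)
  f <- 3e13 / sum(g$area[g$active])
  expect_equal(total_pore_volume(g2), f * total_pore_volume(g),
               tolerance = 1e-12)
  expect_error(rescale_area(g, -1), "positive")
})
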