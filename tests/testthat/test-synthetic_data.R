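test_that("generated grids satisfy every margin-grid invariant", {
  g <- simulate_margin_grid(20, 40, seed = 14)
  expect_s3_class(g, "margin_grid")
  act <- g$active
  expect_true(all(g$depth[act] > 0 & g$depth[act] <= 1000))
  expect_true(all(g$porosity >= 0 & g$porosity <= 1))
  expect_true(all(g$temperature[act] >= 271.15 &
                    g$temperature[act] <= 303.15))
  expect_true(all(g$opd[act] > 0))
  expect_true(all(g$area > 0))
  expect_equal(g$pore_volume[act],
               g$porosity[act] * g$opd[act] * g$area[act],
               tolerance = 1e-12)
  expect_true(all(g$pore_volume[!act] == 0))
})

test_that("shelf_fraction = 1 confines active depths to the shelf", {
  g <- simulate_margin_grid(10, 10, shelf_fraction = 1, seed = 2)
  expect_true(all(g$depth[g$active] <= 200))
  g2 <- simulate_margin_grid(10, 10, shelf_fraction = 0, seed = 2)
  expect_true(all(g2$depth[g2$active] >= 200))
})

test_that("grid generation is deterministic in its seed", {
  a <- simulate_margin_grid(12, 12, seed = 5)
  b <- simulate_margin_grid(12, 12, seed = 5)
  expect_identical(a$depth, b$depth)
  expect_identical(a$pore_volume, b$pore_volume)
  c <- simulate_margin_grid(12, 12, seed = 6)
  expect_false(identical(a$depth, c$depth))
})

test_that("default grid scaled to the real margin area lands near the reported pore volume", {
  g <- simulate_margin_grid(seed = 1, total_active_area_m2 = 3e13)
  pv_l <- total_pore_volume(g, unit = "l")
  # order-of-magnitude gate against the reported 1.2e14 l
  expect_gt(pv_l, 1.2e13)
  expect_lt(pv_l, 1.2e15)
})

test_that("noise-free incubations are recovered exactly by the rate fit", {
  s <- simulate_incubation(true_slope = 29.0, intercept = 1,
                           noise_sd = 0, seed = 1)
  f <- fit_rate(s)
  expect_equal(f$slope, 29.0, tolerance = 1e-9)
  expect_equal(f$stderr, 0, tolerance = 1e-9)
})

test_that("the catalyst-free control rate is recovered under small noise", {
  slopes <- vapply(1:100, function(seed) {
    fit_rate(simulate_incubation(true_slope = 0.2, intercept = 0.05,
                                 noise_sd = 0.001, seed = seed))$slope
  }, numeric(1))
  sem <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.2), 3 * sem)
})

test_that("doubling the noise roughly doubles the fitted standard error", {
  se_at <- function(noise) {
    mean(vapply(1:100, function(seed) {
      fit_rate(simulate_incubation(true_slope = 21.4, intercept = 1,
                                   noise_sd = noise, seed = seed))$stderr
    }, numeric(1)))
  }
  ratio <- se_at(0.01) / se_at(0.005)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("emulated published conditions reproduce the printed slopes and SEs", {
  ser <- simulate_reported_incubations(seed = 10)
  tbl <- reported_rates()
  fits <- fit_rates_table(ser[tbl$condition_label])
  # slopes within 3 printed SEs; fitted SEs on the printed scale
  expect_true(all(abs(fits$slope_nmol_l_yr - tbl$rate_nmol_l_yr) <=
                    3 * tbl$se_nmol_l_yr))
  expect_true(all(fits$stderr_nmol_l_yr < 3 * tbl$se_nmol_l_yr))
})

test_that("DLS radius draws follow the reported triangular support and peak", {
  x <- simulate_dls_radii(2e4, seed = 3)
  expect_true(all(x >= 3.25 & x <= 4.36))
  # triangular moments: mean (lo+peak+hi)/3, sd from the closed form
  tri_mean <- (3.25 + 3.77 + 4.36) / 3
  tri_sd <- sqrt((3.25^2 + 3.77^2 + 4.36^2 - 3.25 * 3.77 - 3.25 * 4.36 -
                    3.77 * 4.36) / 18)
  expect_lt(abs(mean(x) - tri_mean), 3 * tri_sd / sqrt(length(x)))
  expect_lt(abs(sd(x) - tri_sd), 0.01)
  # mode near the reported peak intensity
  dens <- density(x)
  expect_lt(abs(dens$x[which.max(dens$y)] - 3.77), 0.15)
  # near-degenerate configuration collapses to the peak
  y <- simulate_dls_radii(100, lo_nm = 3.769, peak_nm = 3.77,
                          hi_nm = 3.771, seed = 1)
  expect_true(all(abs(y - 3.77) < 0.002))
  expect_error(simulate_dls_radii(10, lo_nm = 4, peak_nm = 3.5), "lo_nm <")
  expect_identical(simulate_dls_radii(50, seed = 4),
                   simulate_dls_radii(50, seed = 4))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_margin_grid(5, 5, seed = 1))
  invisible(simulate_incubation(5, seed = 1))
  invisible(simulate_dls_radii(10, seed = 1))
  expect_identical(.Random.seed, before)
})
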