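test_that("range construction widens by one SD and clamps at the 1e-15 floor", {
  r <- build_range(c(21.4, 29.0), 5.1, "rate")
  expect_equal(r$lo, 16.3)
  expect_equal(r$hi, 34.1)
  expect_equal(r$sd_used, 5.1)
  clamped <- build_range(0.1, 0.5, "rate")
  expect_equal(clamped$lo, 1e-15)
  expect_equal(clamped$hi, 0.6)
  nosd <- build_range(c(2, 5), 0, "c_content")
  expect_equal(c(nosd$lo, nosd$hi), c(2, 5))
  expect_error(build_range(numeric(0), 1), "non-empty")
  expect_error(build_range(c(1, NA), 1), "non-empty finite")
  expect_error(build_range(1, -1), "sd")
})

test_that("uniform sampling stays on its support with the right mean", {
  r <- build_range(c(2, 4), 1, "molecular_weight")
  set.seed(123)
  x <- sample_uniform(r, 1e5)
  expect_true(all(x >= r$lo & x <= r$hi))
  se <- (r$hi - r$lo) / sqrt(12) / sqrt(length(x))
  expect_lt(abs(mean(x) - (r$lo + r$hi) / 2), 3 * se)
  deg <- build_range(3, 0, "c_content")
  deg$hi <- deg$lo
  expect_equal(sample_uniform(deg, 10), rep(deg$lo, 10))
})

degenerate_ranges <- function() {
  list(rate = build_range(29.0, 0, "rate"),
       activation_energy = build_range(1e5, 0, "activation_energy"),
       molecular_weight = build_range(2e5, 0, "molecular_weight"),
       c_content = build_range(0.4, 0, "c_content"))
}

test_that("degenerate ranges collapse every run to the deterministic value", {
  g <- make_uniform_grid(5, 5, depth = 150, temp_K = 277.15)
  p <- upscale_params(rate_nmol_l_yr = 29.0, e_a = 1e5, mw = 2e5,
                      c_content = 0.4)
  det <- global_c_pres(g, p)
  for (mode in c("shared_draws", "per_cell_draws")) {
    mc <- run_mc(g, degenerate_ranges(), n_runs = 50, seed = 4, mode = mode)
    expect_equal(unique(mc$per_run_totals), det, tolerance = 1e-12)
    expect_equal(mc$ci_hi - mc$ci_lo, 0, tolerance = 1e-15)
  }
})

test_that("the same seed reproduces every field bit-identically", {
  g <- simulate_margin_grid(8, 12, seed = 2)
  for (mode in c("shared_draws", "per_cell_draws")) {
    a <- run_mc(g, n_runs = 100, seed = 77, mode = mode)
    b <- run_mc(g, n_runs = 100, seed = 77, mode = mode)
    expect_identical(a$per_run_totals, b$per_run_totals)
    expect_identical(a$per_cell_mean, b$per_cell_mean)
    expect_identical(a$mean, b$mean)
  }
  a <- run_mc(g, n_runs = 100, seed = 77)
  b <- run_mc(g, n_runs = 100, seed = 78)
  expect_false(identical(a$per_run_totals, b$per_run_totals))
})

test_that("run_mc leaves the caller's RNG state untouched", {
  set.seed(31)
  before <- .Random.seed
  invisible(run_mc(make_uniform_grid(3, 3), n_runs = 20, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("shared-draws MC mean agrees with the quadrature expectation", {
  g <- simulate_margin_grid(6, 6, active_fraction = 1, seed = 9)
  ranges <- default_parameter_ranges()
  mc <- run_mc(g, ranges, n_runs = 1000, seed = 21)
  oracle <- mc_oracle_mean_tg(g, ranges)
  se <- mc$sd / sqrt(mc$n_runs)
  expect_lt(abs(mc$mean - oracle), 3 * se)
})

test_that("t-interval matches the textbook formula and brackets the mean", {
  set.seed(5)
  x <- rnorm(1000)
  ci <- confidence_interval(x, 0.95)
  half <- qt(0.975, 999) * sd(x) / sqrt(1000)
  expect_equal(ci$ci_lo, mean(x) - half, tolerance = 1e-12)
  expect_equal(ci$ci_hi, mean(x) + half, tolerance = 1e-12)
  expect_true(ci$ci_lo <= ci$mean && ci$mean <= ci$ci_hi)
  expect_equal(ci$percentile_lo, unname(quantile(x, 0.025)))
  expect_equal(confidence_interval(rep(2, 10))$ci_hi -
                 confidence_interval(rep(2, 10))$ci_lo, 0)
  expect_error(confidence_interval(1), "degenerate")
})

test_that("CI width shrinks roughly as one over the square root of n_runs", {
  g <- make_uniform_grid(5, 5, depth = 300, temp_K = 276.15)
  widths <- vapply(c(250, 1000, 4000), function(n) {
    mc <- run_mc(g, n_runs = n, seed = 13)
    mc$ci_hi - mc$ci_lo
  }, numeric(1))
  expo <- coef(lm(log(widths) ~ log(c(250, 1000, 4000))))[2]
  expect_gt(expo, -0.6)
  expect_lt(expo, -0.4)
})

test_that("parametric spread persists under grid refinement only in shared mode", {
  coarse <- make_uniform_grid(4, 4, depth = 200, temp_K = 277.15,
                              lat_range = c(0, 8), lon_range = c(0, 8))
  fine <- make_uniform_grid(16, 16, depth = 200, temp_K = 277.15,
                            lat_range = c(0, 8), lon_range = c(0, 8))
  cov_of <- function(g, mode) {
    mc <- run_mc(g, n_runs = 400, seed = 3, mode = mode)
    sd(mc$per_run_totals) / mean(mc$per_run_totals)
  }
  cs <- cov_of(coarse, "shared_draws")
  fs <- cov_of(fine, "shared_draws")
  # same global parameter draws, same total PV: spread does not average out
  expect_equal(fs, cs, tolerance = 1e-6)
  cp <- cov_of(coarse, "per_cell_draws")
  fp <- cov_of(fine, "per_cell_draws")
  # 16x the cells: per-cell parameter noise averages out ~4x
  expect_lt(fp, 0.5 * cp)
})

test_that("no sampled value ever breaches the clamp floor", {
  r <- build_range(0.01, 1, "rate")  # lo clamped to 1e-15
  set.seed(8)
  x <- sample_uniform(r, 1e5)
  expect_true(all(x >= 1e-15))
})

test_that("estimator methods expose the mean, interval and draws", {
  g <- make_uniform_grid(3, 3)
  mc <- run_mc(g, n_runs = 100, seed = 6)
  expect_named(coef(mc), "global_mean_Tg")
  ci <- confint(mc)
  expect_equal(unname(ci[1, ]), c(mc$ci_lo, mc$ci_hi))
  ci90 <- confint(mc, level = 0.90)
  expect_true(ci90[1, 1] > ci[1, 1] && ci90[1, 2] < ci[1, 2])
  expect_output(print(mc), "Monte Carlo global GPS carbon preservation")
  expect_error(run_mc(g, list(rate = build_range(1, 0, "rate")),
                      n_runs = 10),
               "ranges must contain")
})
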