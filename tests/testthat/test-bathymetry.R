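test_that("the variance quadratic matches a brute-force polynomial oracle", {
  cf <- c(0.238, 10.805, -18.353)
  oracle <- function(x) {
    y <- vapply(x, function(xi) sum(cf * xi^(0:2)), numeric(1))
    pmax(y, 0)
  }
  expect_equal(water_column_variance(0), 0.238)
  expect_equal(water_column_variance(0.1), 1.13497, tolerance = 1e-12)

  set.seed(99)
  x <- runif(1000, -1, 1.5)
  expect_equal(water_column_variance(x), oracle(x), tolerance = 1e-15)

  # analytic vertex: maximum ~1.8283 at x ~0.29437
  opt <- optimize(function(x) -water_column_variance(x), c(-1, 1))
  expect_equal(opt$minimum, 10.805 / (2 * 18.353), tolerance = 1e-6)
  expect_equal(-opt$objective, 1.8283, tolerance = 1e-4)
  expect_equal(water_column_variance(10.805 / (2 * 18.353)),
               0.238 + 10.805^2 / (4 * 18.353), tolerance = 1e-12)
})

test_that("equal blue and green reflectance gives index 1 at any albedo", {
  g <- tiny_grid(40)
  for (a in c(0.05, 0.3, 0.8)) {
    cube <- flat_cube(a, c(2, 2), g)
    dm <- relative_depth_log_ratio(cube)
    expect_true(all(dm$valid))
    expect_true(all(abs(dm$values - 1) < 1e-12))
  }
})

test_that("unstable pixels are flagged invalid, not NaN storms", {
  g <- tiny_grid(40)
  cube <- flat_cube(0.3, c(2, 2), g)
  cube$values[1, 1, ] <- 0        # ln argument <= 1
  cube$values[2, 2, ] <- 5e-4     # 1000 * R < 1
  dm <- relative_depth_log_ratio(cube)
  expect_false(dm$valid[1, 1])
  expect_false(dm$valid[2, 2])
  expect_true(dm$valid[1, 2])
  expect_true(all(is.na(dm$values[!dm$valid])))
  expect_true(all(is.finite(dm$values[dm$valid])))
})

test_that("relative depth tracks true depth on zero-noise bottoms", {
  g <- tiny_grid(80)
  sc <- small_reef(shape = c(64, 64), classes = "benthos", noise_sd = 0,
                   grid = g)
  dm <- relative_depth_log_ratio(sc$refl)
  sel <- dm$valid
  rho <- cor(dm$values[sel], sc$truth$depth[sel], method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("albedo changes move the index far less than a 1 m depth change", {
  g <- tiny_grid(80)
  lib <- synth_endmembers("Acropora", 1:6, seed = 1, grid = g)
  water <- make_water_model(g)
  truth <- make_scene(c(10, 10), "sand", 0, 1, library = lib)
  idx_at <- function(label, depth) {
    truth$labels[] <- label
    truth$depth[] <- depth
    rend <- render_cube(truth, water, noise_sd = 0)
    dm <- relative_depth_log_ratio(to_reflectance(rend$cube, rend$white))
    mean(dm$values[dm$valid])
  }
  albedo_spread <- abs(idx_at("sand", 1.5) - idx_at("benthos", 1.5))
  depth_spread <- abs(idx_at("sand", 2.5) - idx_at("sand", 1.5))
  expect_lt(albedo_spread, depth_spread)
  # paper-style claim: bright sand vs dark bottom at identical depth stays
  # within a small fraction of the scene's index range
  idx_range <- abs(idx_at("sand", 3) - idx_at("sand", 0))
  expect_lt(albedo_spread, 0.25 * idx_range)
})

test_that("calibration recovers an exact linear depth-index relation", {
  vals <- matrix(seq(0.9, 1.1, length.out = 25), 5, 5)
  relmap <- structure(list(values = vals, valid = matrix(TRUE, 5, 5),
                           calibrated = FALSE, calibration = NULL),
                      class = "depth_map")
  # survey depths exactly linear in the index: depth = -18 + 20 * idx
  tab <- data.frame(depth = -18 + 20 * vals[cbind(1:5, 1:5)],
                    pixel_x = 0:4, pixel_y = 0:4)
  cal <- calibrate_depth(relmap, tab)
  expect_true(cal$calibrated)
  expect_equal(cal$calibration$slope, 20, tolerance = 1e-9)
  expect_equal(cal$calibration$intercept, -18, tolerance = 1e-9)
  expect_lt(cal$calibration$rmse, 1e-9)
  expect_equal(cal$values, pmax(-18 + 20 * vals, 0), tolerance = 1e-9)

  expect_error(calibrate_depth(relmap, tab[1, ]), ">= 2")
  flat <- relmap
  flat$values[] <- 1
  expect_error(calibrate_depth(flat, tab), "degenerate")
})

test_that("calibrated synthetic depths recover truth within 5% of range", {
  g <- tiny_grid(80)
  sc <- small_reef(shape = c(48, 48), classes = "benthos", noise_sd = 0,
                   grid = g)
  dm <- relative_depth_log_ratio(sc$refl)
  tab <- data.frame(depth = sc$truth$depth[cbind(seq(2, 46, by = 4),
                                                 seq(2, 46, by = 4))],
                    pixel_x = seq(2, 46, by = 4) - 1L,
                    pixel_y = seq(2, 46, by = 4) - 1L)
  cal <- calibrate_depth(dm, tab)
  mae <- mean(abs(cal$values[cal$valid] - sc$truth$depth[cal$valid]))
  expect_lte(mae, 0.05 * max(sc$truth$depth))
})

test_that("water-column correction rescales by the variance share", {
  g <- tiny_grid(20)
  cube <- flat_cube(0.4, c(2, 2), g)

  # y floored to 0 leaves the spectrum unchanged
  x0 <- matrix(-1, 2, 2)
  expect_equal(depth_correct(cube, x0)$values, cube$values)

  # uniform y at the quadratic's maximum multiplies by 1/0.981717
  xv <- 10.805 / (2 * 18.353)
  y <- water_column_variance(xv)
  corr <- depth_correct(cube, matrix(xv, 2, 2))
  expect_equal(corr$values[1, 1, 1], 0.4 / (1 - y / 100), tolerance = 1e-12)
  expect_equal(corr$values[1, 1, 1], 0.4 / 0.981717, tolerance = 1e-5)
  expect_false(any(attr(corr, "capped")))
})

test_that("correction narrows the 1 m vs 2.3 m same-class divergence", {
  # study conditions: the full sensor grid and a pigmented (unbleached)
  # coral class, whose green/blue log-ratio sits inside the variance
  # quadratic's responsive window
  g <- make_wavelength_grid(274, 400, 1000)
  lib <- synth_endmembers("Porites massive", 1:6, seed = 4, grid = g)
  water <- make_water_model(g)
  truth <- make_scene(c(2, 2), "sand", 0, 1, library = lib)
  truth$labels[] <- "Porites massive lv6"
  truth$depth[, 1] <- 1
  truth$depth[, 2] <- 2.3
  rend <- render_cube(truth, water, noise_sd = 0)
  refl <- to_reflectance(rend$cube, rend$white)
  corr <- depth_correct(refl)

  # mechanism: the deeper pixel receives the larger variance share, hence
  # the larger rescale
  b480 <- nearest_band(g, 480)
  b540 <- nearest_band(g, 540)
  xs <- log(refl$values[, , b540] / refl$values[, , b480])
  expect_gt(water_column_variance(xs[1, 2]), water_column_variance(xs[1, 1]))

  before <- mean(abs(refl$values[1, 1, ] - refl$values[1, 2, ]))
  after <- mean(abs(corr$values[1, 1, ] - corr$values[1, 2, ]))
  expect_lt(after, before)
})
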