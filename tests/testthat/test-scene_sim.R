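test_that("wavelength grid is uniform with the sensor's spacing", {
  g <- make_wavelength_grid(274, 400, 1000)
  expect_length(g, 274)
  expect_equal(g[1], 400)
  expect_equal(g[274], 1000)
  sp <- diff(g)
  expect_true(all(abs(sp - 600 / 273) < 1e-12))
  expect_false(is.unsorted(g, strictly = TRUE))

  expect_equal(as.numeric(make_wavelength_grid(2, 400, 1000)), c(400, 1000))
  expect_error(make_wavelength_grid(1, 400, 1000), "n_bands")
  expect_error(make_wavelength_grid(10, 1000, 400), "lambda_min")
})

test_that("band nearest 540 nm matches an exhaustive search", {
  g <- make_wavelength_grid(274, 400, 1000)
  oracle <- which.min(abs(as.numeric(g) - 540))
  b <- nearest_band(g, 540)
  expect_equal(b, oracle)
  expect_equal(b, 65L)  # zero-based band 64
  expect_equal(as.numeric(g[b]), 540.6593, tolerance = 1e-6)
})

test_that("endmember brightness is strictly ordered over bleaching levels", {
  g <- tiny_grid()
  for (seed in c(1, 7)) {
    lib <- synth_endmembers(c("Acropora", "Porites massive"), 1:6,
                            seed = seed, grid = g)
    for (genus in c("Acropora", "Porites massive")) {
      means <- vapply(1:6, function(lv) {
        mean(lib$spectra[, coral_class_label(genus, lv)])
      }, numeric(1))
      expect_true(all(diff(means) < 0))
    }
    expect_true(all(lib$spectra >= 0 & lib$spectra <= 1))
  }
})

test_that("bleached endmembers are elevated near 400 and 750 nm", {
  g <- tiny_grid(120)
  lib <- synth_endmembers("Acropora", c(1, 2, 5, 6), seed = 1, grid = g)
  for (nm in c(400, 750)) {
    b <- nearest_band(g, nm)
    for (lv_b in 1:2) {
      for (lv_u in 5:6) {
        expect_gt(lib$spectra[b, coral_class_label("Acropora", lv_b)],
                  lib$spectra[b, coral_class_label("Acropora", lv_u)])
      }
    }
  }
})

test_that("endmember synthesis is deterministic and rejects empty genera", {
  g <- tiny_grid()
  a <- synth_endmembers(c("A", "B"), c(1, 6), seed = 42, grid = g)
  b <- synth_endmembers(c("A", "B"), c(1, 6), seed = 42, grid = g)
  expect_identical(a, b)
  expect_error(synth_endmembers(character(0), 1:6, 1, g), "nonempty")
  expect_error(synth_endmembers("A", c(0, 7), 1, g), "subset")
})

test_that("scenes honour class, depth and determinism contracts", {
  g <- tiny_grid()
  lib <- synth_endmembers("Acropora", 1:6, seed = 1, grid = g)

  t1 <- make_scene(c(16, 16), "sand", max_depth = 3, seed = 0,
                   library = lib)
  expect_true(all(t1$labels == "sand"))

  classes <- paste0("Acropora lv", 1:6)
  t2 <- make_scene(c(64, 64), classes, max_depth = 6, seed = 3,
                   library = lib)
  expect_true(all(classes %in% t2$labels))
  expect_equal(min(t2$depth), 0)
  expect_equal(max(t2$depth), 6)
  expect_identical(dim(t2$labels), dim(t2$depth))

  t3 <- make_scene(c(64, 64), classes, max_depth = 6, seed = 3,
                   library = lib)
  expect_identical(t2, t3)

  expect_error(make_scene(c(1, 2), classes, 6, 1, library = lib), "pixels")
})

test_that("rendering reduces to bottom reflectance plus offset at depth 0", {
  sc <- small_reef()
  truth0 <- sc$truth
  truth0$depth[] <- 0
  rend <- render_cube(truth0, sc$water, noise_sd = 0, seed = 1)
  refl <- to_reflectance(rend$cube, rend$white)
  i <- 5; j <- 9
  want <- sc$lib$spectra[, truth0$labels[i, j]] + sc$water$offset
  expect_equal(pixel_spectrum(refl, i - 1, j - 1), pmin(want, 1),
               tolerance = 1e-6)
})

test_that("reflectance conversion inverts the rendering illumination", {
  sc <- small_reef(noise_sd = 0)
  # recover R_obs per pixel to float32-write precision
  d <- dim(sc$cube$values)
  att <- exp(-2 * outer(as.numeric(sc$truth$depth), sc$water$k))
  lab <- as.character(sc$truth$labels)
  r_obs <- t(sc$lib$spectra[, lab]) * att +
    matrix(sc$water$offset, nrow(att), d[3], byrow = TRUE)
  got <- matrix(sc$refl$values, d[1] * d[2], d[3])
  expect_equal(got, pmin(r_obs, 1), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("observed band-mean reflectance is non-increasing in depth", {
  g <- tiny_grid(80)
  lib <- synth_endmembers("Acropora", 1:6, seed = 2, grid = g)
  water <- make_water_model(g)
  depths <- seq(0, 5, by = 0.5)
  truth <- make_scene(c(1, length(depths)), "sand", max_depth = 0, seed = 0,
                      library = lib)
  truth$labels[] <- "Acropora lv4"
  truth$depth[1, ] <- depths
  rend <- render_cube(truth, water, noise_sd = 0, seed = 0)
  refl <- to_reflectance(rend$cube, rend$white)
  means <- apply(refl$values[1, , ], 1, mean)
  expect_true(all(diff(means) < 0))

  # depth effect: spectral distance from the 1 m spectrum grows with delta-z
  s1 <- refl$values[1, which(depths == 1), ]
  dist_to_1m <- apply(refl$values[1, , ], 1, function(s)
    sqrt(sum((s - s1)^2)))
  deeper <- depths >= 1
  expect_true(all(diff(dist_to_1m[deeper]) > 0))
})

test_that("survey tables sample coral truth faithfully", {
  sc <- small_reef(shape = c(64, 64),
                   classes = c(paste0("Acropora lv", 1:6)))
  tab <- make_survey_table(sc$truth, 64, seed = 5)
  expect_equal(nrow(tab), 64)
  for (i in seq_len(nrow(tab))) {
    truth_label <- sc$truth$labels[tab$pixel_y[i] + 1, tab$pixel_x[i] + 1]
    expect_identical(coral_class_label(tab$coral_type[i],
                                       tab$bleaching_level[i]),
                     truth_label)
    expect_equal(tab$depth[i],
                 round(sc$truth$depth[tab$pixel_y[i] + 1,
                                      tab$pixel_x[i] + 1], 2))
  }
  # every coral class present in the scene is represented
  expect_setequal(unique(coral_class_label(tab$coral_type,
                                           tab$bleaching_level)),
                  intersect(unique(c(sc$truth$labels)),
                            paste0("Acropora lv", 1:6)))

  # lat/lon round-trips through the geotransform to the sampled pixel
  px <- geo_to_pixel(sc$truth$gt, tab$latitude, tab$longitude)
  expect_identical(px$row, tab$pixel_y)
  expect_identical(px$col, tab$pixel_x)

  expect_identical(make_survey_table(sc$truth, 0, 1),
                   make_survey_table(sc$truth, 0, 2))
  expect_equal(nrow(make_survey_table(sc$truth, 0, 1)), 0)
  expect_identical(make_survey_table(sc$truth, 30, 9),
                   make_survey_table(sc$truth, 30, 9))

  sand_only <- make_scene(c(8, 8), "sand", 3, 1, library = sc$lib)
  expect_error(make_survey_table(sand_only, 4, 1), "no coral")
})

test_that("spume polygons relabel exactly the covered pixels", {
  sc <- small_reef(shape = c(32, 32))
  expect_identical(add_spume(sc$truth, list()), sc$truth)

  gt <- sc$truth$gt
  # axis-aligned square spanning pixel centers rows/cols 5..14
  corners_rc <- rbind(c(4.5, 4.5), c(4.5, 14.5), c(14.5, 14.5), c(14.5, 4.5))
  geo <- pixel_to_geo(gt, corners_rc[, 1], corners_rc[, 2])
  poly <- list(data.frame(lat = geo$lat, lon = geo$lon))
  spumed <- add_spume(sc$truth, poly)
  expect_equal(sum(spumed$labels == "spume"), 100)
  expect_true(all(spumed$labels[6:15, 6:15] == "spume"))

  # whole-scene polygon saturates
  big_rc <- rbind(c(-1, -1), c(-1, 32), c(32, 32), c(32, -1))
  geo2 <- pixel_to_geo(gt, big_rc[, 1], big_rc[, 2])
  all_sp <- add_spume(sc$truth, list(data.frame(lat = geo2$lat,
                                                lon = geo2$lon)))
  expect_true(all(all_sp$labels == "spume"))

  # polygon covering no pixel center warns and changes nothing
  out_rc <- rbind(c(-9, -9), c(-9, -5), c(-5, -5), c(-5, -9))
  geo3 <- pixel_to_geo(gt, out_rc[, 1], out_rc[, 2])
  expect_warning(unchanged <- add_spume(sc$truth,
                                        list(data.frame(lat = geo3$lat,
                                                        lon = geo3$lon))),
                 "no pixel center")
  expect_identical(unchanged$labels, sc$truth$labels)
})

test_that("rendering is deterministic under a fixed seed", {
  sc <- small_reef(noise_sd = 0.02, seed = 9)
  sc2 <- small_reef(noise_sd = 0.02, seed = 9)
  expect_identical(sc$cube$values, sc2$cube$values)
  expect_true(all(sc$cube$values >= 0))

  # grid mismatch between truth and water model is a shape error
  other <- make_water_model(tiny_grid(41))
  expect_error(render_cube(sc$truth, other), "grids differ")
})
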