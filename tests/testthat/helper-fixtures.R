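# shared fixtures: everything is generated in code, no stored binaries

tiny_grid <- function(n = 60) make_wavelength_grid(n, 400, 1000)

# a flat-spectrum reflectance cube
flat_cube <- function(value = 0.4, shape = c(3, 3), grid = tiny_grid()) {
  spectral_cube(array(value, c(shape, length(grid))), grid,
                north_up_transform(10, 20, 0.001), "reflectance")
}

# cube whose every pixel carries the given spectrum
spectrum_cube <- function(spec, shape = c(2, 2), grid = tiny_grid(),
                          kind = "reflectance") {
  b <- length(spec)
  stopifnot(b == length(grid))
  v <- aperm(array(rep(spec, prod(shape)), c(b, shape)), c(2, 3, 1))
  spectral_cube(v, grid, north_up_transform(10, 20, 0.001), kind)
}

# small rendered scene used by several suites
small_reef <- function(shape = c(48, 48), classes = c("Acropora lv1",
                                                      "Acropora lv6"),
                       max_depth = 3, noise_sd = 0, seed = 7,
                       grid = tiny_grid(80)) {
  info <- parse_class_label(classes)
  genera <- unique(stats::na.omit(info$genus))
  if (!length(genera)) genera <- "Acropora"
  lib <- synth_endmembers(genera, 1:6, seed = seed, grid = grid)
  truth <- make_scene(shape, classes, max_depth, seed = seed, library = lib)
  water <- make_water_model(grid)
  rend <- render_cube(truth, water, noise_sd = noise_sd, seed = seed + 1)
  list(truth = truth, water = water, cube = rend$cube, white = rend$white,
       refl = to_reflectance(rend$cube, rend$white), grid = grid, lib = lib)
}

# brute-force even-odd-rule point-in-polygon, independent of mgcv
pip_oracle <- function(py, px, poly_y, poly_x) {
  n <- length(poly_y)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly_y[i] > py) != (poly_y[j] > py) &&
        px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
          (poly_y[j] - poly_y[i]) + poly_x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
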