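test_that("the RBF kernel honours its closed form and constraints", {
  set.seed(1)
  x <- runif(20)
  expect_equal(rbf_kernel(x, x, 2), 1)

  # ||xi - xj||^2 = 1, gamma = 1 -> exp(-1)
  xi <- rep(0, 4)
  xj <- c(1, 0, 0, 0)
  expect_equal(rbf_kernel(xi, xj, 1), exp(-1))
  expect_equal(rbf_kernel(xi, xj, 1), 0.367879, tolerance = 1e-5)

  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_identical(rbf_kernel(a, b, 0.7), rbf_kernel(b, a, 0.7))
    expect_true(rbf_kernel(a, b, 0.7) > 0 && rbf_kernel(a, b, 0.7) <= 1)
  }
  expect_error(rbf_kernel(xi, xj, 0), "> 0")
  expect_error(rbf_kernel(xi, xj, -1), "> 0")
  expect_error(rbf_kernel(xi, c(xj, 1), 1), "length")
})

test_that("Gram matrices are symmetric positive semidefinite", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 12
    x <- matrix(rnorm(n * 8), n, 8)
    gam <- runif(1, 0.1, 3)
    K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      rbf_kernel(x[i, ], x[j, ], gam)
    }))
    expect_equal(K, t(K))
    expect_true(all(eigen(K, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("training separates constant spectra and is deterministic", {
  x <- rbind(matrix(0.2, 5, 10), matrix(0.8, 5, 10))
  x <- x + matrix(seq(-0.01, 0.01, length.out = 100), 10, 10)
  labels <- rep(c("dark", "bright"), each = 5)
  model <- train_classifier(x, labels)
  pred <- predict(model$fit, x)
  expect_equal(as.character(pred), labels)

  model2 <- train_classifier(x, labels)
  set.seed(3)
  probe <- matrix(runif(60, 0, 1), 6, 10)
  expect_identical(as.character(predict(model$fit, probe)),
                   as.character(predict(model2$fit, probe)))

  expect_error(train_classifier(x, rep("one", 10)), "degenerate")
  expect_error(train_classifier(x, labels, gamma = -1), "> 0")
})

test_that("noise-free endmember classes resubstitute perfectly", {
  g <- tiny_grid(60)
  lib <- synth_endmembers("Acropora", 1:6, seed = 5, grid = g)
  classes <- paste0("Acropora lv", 1:6)
  # a few jittered copies per class, deterministic jitter
  x <- NULL; labels <- c()
  for (cl in classes) {
    e <- lib$spectra[, cl]
    for (j in 1:3) {
      x <- rbind(x, e + 1e-4 * sin(j * seq_len(60)))
      labels <- c(labels, cl)
    }
  }
  model <- train_classifier(x, labels)
  expect_equal(as.character(predict(model$fit, x)), labels)
})

test_that("prediction maps pure training spectra back to their classes", {
  g <- tiny_grid(30)
  specA <- seq(0.1, 0.3, length.out = 30)
  specB <- seq(0.6, 0.4, length.out = 30)
  x <- rbind(specA, specA + 0.01, specB, specB + 0.01)
  model <- train_classifier(x, c("A", "A", "B", "B"))

  v <- array(0, c(2, 2, 30))
  v[1, 1, ] <- specA; v[2, 1, ] <- specA
  v[1, 2, ] <- specB; v[2, 2, ] <- specB
  cube <- spectral_cube(v, g, NULL, "reflectance")
  cmap <- predict_map(model, cube)
  expect_equal(matrix(cmap$legend[cmap$ids], 2, 2),
               matrix(c("A", "A", "B", "B"), 2, 2))

  # all-masked input yields no predictions
  masked <- predict_map(model, cube, mask = matrix(FALSE, 2, 2))
  expect_true(all(is.na(masked$ids)))
  expect_false(any(masked$valid))

  bad <- spectral_cube(array(0.2, c(2, 2, 10)), tiny_grid(10), NULL,
                       "reflectance")
  expect_error(predict_map(model, bad), "band count")
})

test_that("k-means baseline recovers separated blobs deterministically", {
  g <- tiny_grid(20)
  v <- array(0.2, c(6, 6, 20))
  v[, 4:6, ] <- 0.8
  cube <- spectral_cube(v, g, NULL, "reflectance")
  cm <- unsupervised_baseline(cube, 2, seed = 1)
  expect_equal(length(unique(as.vector(cm$ids[, 1:3]))), 1)
  expect_equal(length(unique(as.vector(cm$ids[, 4:6]))), 1)
  expect_false(cm$ids[1, 1] == cm$ids[1, 6])

  cm2 <- unsupervised_baseline(cube, 2, seed = 1)
  expect_identical(cm$ids, cm2$ids)

  expect_error(unsupervised_baseline(cube, 1, 1), "k")
  expect_error(unsupervised_baseline(cube, 37, 1), "k")
})

test_that("denoise windows of 1 are the identity and constants invariant", {
  sc <- small_reef(shape = c(8, 8), noise_sd = 0.02, grid = tiny_grid(20))
  expect_equal(denoise(sc$refl, 1, 1), sc$refl)

  const <- flat_cube(0.37, c(6, 6), tiny_grid(20))
  for (w in list(c(5, 1), c(1, 3), c(5, 3))) {
    out <- denoise(const, w[1], w[2])
    expect_equal(out$values, const$values, tolerance = 1e-12)
  }
  expect_error(denoise(const, 2, 1), "odd")
  expect_error(denoise(const, 1, 4), "odd")
})

test_that("a single-pixel impulse is removed by the 3x3 spatial median", {
  g <- tiny_grid(3)
  v <- array(0.2, c(5, 5, 3))
  v[3, 3, 2] <- 0.9
  cube <- spectral_cube(v, g, NULL, "reflectance")
  out <- denoise(cube, 1, 3)
  # median of the 3x3 neighborhood: eight 0.2s and one 0.9 -> 0.2
  expect_equal(out$values[3, 3, 2], 0.2)
  expect_equal(out$values[1, 1, 1], 0.2)
})

test_that("the spatial median equals an apply-based oracle", {
  set.seed(4)
  m <- matrix(runif(11 * 7), 11, 7)
  got <- reefbleach:::median_filter2d(m, 3)
  oracle <- m
  for (i in 1:11) {
    for (j in 1:7) {
      rr <- pmin(pmax((i - 1):(i + 1), 1), 11)
      cc <- pmin(pmax((j - 1):(j + 1), 1), 7)
      oracle[i, j] <- median(as.vector(m[rr, cc]))
    }
  }
  expect_equal(got, oracle)
})

test_that("the band smoother matches the reference Savitzky-Golay filter", {
  set.seed(5)
  x <- runif(40)
  S <- reefbleach:::sgolay_matrix(40, 7, p = 2)
  expect_equal(as.numeric(S %*% x), as.numeric(signal::sgolayfilt(x, 2, 7)),
               tolerance = 1e-10)
})

test_that("exclusion masks only ever remove classified pixels", {
  g <- tiny_grid(10)
  v <- array(0.2, c(4, 4, 10))
  v[, 3:4, ] <- 0.8
  cube <- spectral_cube(v, g, NULL, "reflectance")
  x <- rbind(rep(0.2, 10), rep(0.21, 10), rep(0.8, 10), rep(0.79, 10))
  model <- train_classifier(x, c("A", "A", "B", "B"))
  cmap <- predict_map(model, cube)

  expect_identical(apply_exclusion_mask(cmap, matrix(FALSE, 4, 4)), cmap)

  allm <- apply_exclusion_mask(cmap, matrix(TRUE, 4, 4))
  expect_true(all(is.na(allm$ids)))

  # mask covering exactly class B's block
  mask <- matrix(FALSE, 4, 4)
  mask[, 3:4] <- TRUE
  out <- apply_exclusion_mask(cmap, mask)
  cnt <- function(cm, lab) mapped_area_fraction(cm, lab)$found_pixels
  expect_equal(cnt(out, "B"), 0)
  expect_equal(cnt(out, "A"), cnt(cmap, "A"))
  expect_identical(out$legend, cmap$legend)
  expect_error(apply_exclusion_mask(cmap, matrix(TRUE, 3, 3)), "shape")
})
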