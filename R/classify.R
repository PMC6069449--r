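#' Radial basis function kernel
#'
#' `K(xi, xj) = exp(-gamma * ||xi - xj||^2)`, `gamma > 0`: symmetric,
#' bounded in (0, 1], equal to 1 iff the spectra coincide.
#'
#' @param xi,xj Numeric spectra of equal length.
#' @param gamma Positive kernel width parameter.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(xi, xj, gamma) {
  if (length(xi) != length(xj)) {
    stop("spectra have different lengths", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be > 0", call. = FALSE)
  }
  exp(-gamma * sum((xi - xj)^2))
}

default_gamma <- function(x) {
  v <- mean(apply(x, 2, stats::var))
  if (!is.finite(v) || v <= 0) 1 / ncol(x) else 1 / (ncol(x) * v)
}

#' Train an RBF-kernel support vector machine on labelled spectra
#'
#' Fits a maximum-margin classifier with the radial basis kernel,
#' multiclass via one-vs-one voting. Defaults: `gamma` scaled as
#' `1/(n_bands * mean per-band variance)` and cost `C = 10`. Training is
#' deterministic for fixed inputs. (The "gamma" here is the kernel width of
#' the RBF, unrelated to the optional image [gamma_adjust()].)
#'
#' @param x Numeric matrix of training spectra, one row per pixel.
#' @param labels Class labels, one per row; at least 2 distinct classes.
#' @param gamma Kernel parameter (> 0); default scaled from the data.
#' @param C Margin penalty (> 0).
#' @return Object of class `class_model`.
#' @export
train_classifier <- function(x, labels, gamma = NULL, C = 10) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) {
    stop("one label per training spectrum required", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("degenerate training set: need >= 2 classes", call. = FALSE)
  }
  if (is.null(gamma)) gamma <- default_gamma(x)
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be > 0",
                                            call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("`C` must be > 0", call. = FALSE)
  legend <- sort(unique(labels))
  fit <- e1071::svm(x, factor(labels, levels = legend), kernel = "radial",
                    gamma = gamma, cost = C, scale = FALSE)
  structure(list(fit = fit, legend = legend, gamma = gamma, C = C,
                 n_bands = ncol(x)),
            class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("<class_model> RBF SVM, %d classes, %d bands, gamma = %.4g, C = %g\n",
              length(x$legend), x$n_bands, x$gamma, x$C))
  invisible(x)
}

class_map <- function(ids, legend, valid) {
  structure(list(ids = ids, legend = legend, valid = valid),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d, %d classes, %d excluded pixels\n",
              nrow(x$ids), ncol(x$ids), length(x$legend), sum(!x$valid)))
  invisible(x)
}

#' Classify every unmasked pixel of a cube
#'
#' @param model A `class_model`.
#' @param cube A reflectance `spectral_cube` whose band count matches the
#'   training spectra.
#' @param mask Optional logical matrix; `FALSE` pixels are excluded from
#'   prediction.
#' @return A `class_map`: integer id raster (NA where excluded), legend
#'   (id -> class label), and validity mask.
#' @export
predict_map <- function(model, cube, mask = NULL) {
  stopifnot(inherits(model, "class_model"), inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (d[3] != model$n_bands) {
    stop("cube band count does not match training spectra", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d[1:2])) stop("mask shape mismatch", call. = FALSE)
  ids <- matrix(NA_integer_, d[1], d[2])
  if (any(mask)) {
    m <- cube_to_matrix(cube)[as.vector(mask), , drop = FALSE]
    pred <- stats::predict(model$fit, m)
    ids[mask] <- as.integer(pred)
  }
  class_map(ids, model$legend, mask)
}

#' Unsupervised k-means baseline partition
#'
#' Centroid-based clustering of pixel spectra, used to flag regions whose
#' supervised label disagrees with the scene's cluster structure. It never
#' overwrites supervised labels.
#'
#' @param cube A reflectance `spectral_cube`.
#' @param k Number of clusters (>= 2, <= pixel count).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A `class_map` with legend `cluster 1..k`.
#' @export
unsupervised_baseline <- function(cube, k, seed = 0) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  n <- d[1] * d[2]
  if (k < 2 || k > n) {
    stop("`k` must satisfy 2 <= k <= pixel count", call. = FALSE)
  }
  m <- cube_to_matrix(cube)
  km <- with_seed(seed, stats::kmeans(m, centers = k, nstart = 5,
                                      iter.max = 100))
  class_map(matrix(as.integer(km$cluster), d[1], d[2]),
            paste("cluster", seq_len(k)), matrix(TRUE, d[1], d[2]))
}

# --- denoising -------------------------------------------------------------

# band-smoother matrix from Savitzky-Golay coefficients: interior samples
# use the central filter, edges the asymmetric end filters
sgolay_matrix <- function(n_bands, window, p = 2) {
  F <- signal::sgolay(p = min(p, window - 1), n = window)
  S <- matrix(0, n_bands, n_bands)
  half <- (window - 1) / 2
  center <- half + 1
  for (i in seq_len(n_bands)) {
    if (i <= half) {
      S[i, 1:window] <- F[i, ]
    } else if (i > n_bands - half) {
      S[i, (n_bands - window + 1):n_bands] <- F[window - (n_bands - i), ]
    } else {
      S[i, (i - half):(i + half)] <- F[center, ]
    }
  }
  S
}

# exact row-wise median via odd-even transposition sort with pmin/pmax
# (fully vectorized over rows; k = number of columns is small)
rowwise_median <- function(m) {
  k <- ncol(m)
  cols <- lapply(seq_len(k), function(j) m[, j])
  for (pass in seq_len(k)) {
    start <- if (pass %% 2 == 1) 1 else 2
    j <- start
    while (j + 1 <= k) {
      lo <- pmin(cols[[j]], cols[[j + 1]])
      hi <- pmax(cols[[j]], cols[[j + 1]])
      cols[[j]] <- lo
      cols[[j + 1]] <- hi
      j <- j + 2
    }
  }
  if (k %% 2 == 1) {
    cols[[(k + 1) / 2]]
  } else {
    (cols[[k / 2]] + cols[[k / 2 + 1]]) / 2
  }
}

# 2-D median filter with border replication
median_filter2d <- function(m, window) {
  if (window == 1) return(m)
  half <- (window - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  shifts <- expand.grid(dr = -half:half, dc = -half:half)
  stacked <- matrix(0, nr * nc, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    rr <- pmin(pmax(seq_len(nr) + shifts$dr[s], 1L), nr)
    cc <- pmin(pmax(seq_len(nc) + shifts$dc[s], 1L), nc)
    stacked[, s] <- as.vector(m[rr, cc])
  }
  matrix(rowwise_median(stacked), nr, nc)
}

#' Spectral and spatial noise reduction
#'
#' Per-pixel Savitzky-Golay polynomial smoothing along the band axis
#' followed by a per-band spatial median filter (border replication).
#' Windows of 1 are identities.
#'
#' @param cube A `spectral_cube`.
#' @param spectral_window Odd number of bands (>= 1).
#' @param spatial_window Odd window width in pixels (>= 1).
#' @param p Polynomial order of the spectral filter.
#' @return The denoised cube.
#' @export
denoise <- function(cube, spectral_window = 5, spatial_window = 3, p = 2) {
  stopifnot(inherits(cube, "spectral_cube"))
  for (w in c(spectral_window, spatial_window)) {
    if (w < 1 || w %% 2 == 0) {
      stop("denoise windows must be odd and >= 1", call. = FALSE)
    }
  }
  d <- dim(cube$values)
  if (spectral_window > 1) {
    if (spectral_window > d[3]) {
      stop("spectral window exceeds band count", call. = FALSE)
    }
    S <- sgolay_matrix(d[3], spectral_window, p)
    m <- cube_to_matrix(cube) %*% t(S)
    cube <- matrix_to_cube(m, cube)
  }
  if (spatial_window > 1) {
    for (b in seq_len(d[3])) {
      cube$values[, , b] <- median_filter2d(cube$values[, , b],
                                            spatial_window)
    }
  }
  if (cube$kind == "reflectance") {
    cube$values[] <- pmin(pmax(cube$values, 0), 1)
  }
  cube
}

#' Exclude masked pixels from a class map
#'
#' Pixels where `mask` is `TRUE` (e.g. inside spume polygons) become
#' excluded; the legend is unchanged and no class gains pixels.
#'
#' @param cmap A `class_map`.
#' @param mask Logical matrix, `TRUE` = exclude.
#' @return The masked `class_map`.
#' @export
apply_exclusion_mask <- function(cmap, mask) {
  stopifnot(inherits(cmap, "class_map"))
  if (!all(dim(mask) == dim(cmap$ids))) {
    stop("mask shape does not match class map", call. = FALSE)
  }
  cmap$ids[mask] <- NA_integer_
  cmap$valid <- cmap$valid & !mask
  cmap
}
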