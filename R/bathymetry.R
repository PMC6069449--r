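#' Water-column variance model
#'
#' A fitted quadratic links the log-transformed green/blue reflectance
#' ratio `x` at a pixel to the percentage of spectral-signature variance
#' attributable to the water column:
#' `y = -18.353 x^2 + 10.805 x + 0.238`, floored at 0. The model also
#' carries the blue and green reference wavelengths used to form the ratio.
#'
#' @param a,b,c Quadratic coefficients (defaults are the published fit).
#' @param blue_nm,green_nm Reference wavelengths (blue < green).
#' @return Object of class `water_column_model`.
#' @export
water_column_model <- function(a = -18.353, b = 10.805, c = 0.238,
                               blue_nm = 480, green_nm = 540) {
  if (!all(is.finite(c(a, b, c)))) stop("coefficients must be finite",
                                        call. = FALSE)
  if (blue_nm >= green_nm) stop("require blue_nm < green_nm", call. = FALSE)
  structure(list(a = a, b = b, c = c, blue_nm = blue_nm,
                 green_nm = green_nm), class = "water_column_model")
}

#' Percent spectral variance due to the water column
#'
#' Evaluates the fitted quadratic at the log-transformed green/blue ratio
#' `x`, floored at 0 (a negative variance share is meaningless).
#'
#' @param x Log-transformed green/blue reflectance ratio (vectorized).
#' @param model A `water_column_model`.
#' @return Percent variance, same length as `x`.
#' @export
water_column_variance <- function(x, model = water_column_model()) {
  stopifnot(inherits(model, "water_column_model"))
  pmax(model$a * x^2 + model$b * x + model$c, 0)
}

#' Relative depth from the blue/green log ratio
#'
#' Per pixel, the relative (uncalibrated) depth index is
#' `ln(n R_blue) / ln(n R_green)` at the grid bands nearest the model's
#' reference wavelengths, with stretch factor `n` keeping both logarithm
#' arguments above 1. Because diffuse attenuation is stronger in the green
#' than the blue, the index increases monotonically with depth, and the
#' ratio-of-logs form largely cancels bottom-albedo brightness. Pixels where
#' either logarithm argument is <= 1 are flagged invalid rather than
#' propagated as NaN.
#'
#' @param cube A reflectance `spectral_cube` covering both reference
#'   wavelengths.
#' @param model A `water_column_model`.
#' @param stretch_n Positive stretch factor (default 1000).
#' @return Object of class `depth_map`: list with `values` (matrix; `NA`
#'   where invalid), `valid` (logical matrix), `calibrated = FALSE`.
#' @export
relative_depth_log_ratio <- function(cube, model = water_column_model(),
                                     stretch_n = 1000) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance") {
    stop("depth estimation requires a reflectance cube", call. = FALSE)
  }
  if (!is.finite(stretch_n) || stretch_n <= 0) {
    stop("`stretch_n` must be positive", call. = FALSE)
  }
  rb <- band_slice(cube, model$blue_nm) * stretch_n
  rg <- band_slice(cube, model$green_nm) * stretch_n
  valid <- rb > 1 & rg > 1
  vals <- matrix(NA_real_, nrow(rb), ncol(rb))
  vals[valid] <- log(rb[valid]) / log(rg[valid])
  structure(list(values = vals, valid = valid, calibrated = FALSE,
                 calibration = NULL),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d, %s, %d invalid pixels\n",
              nrow(x$values), ncol(x$values),
              if (x$calibrated) "calibrated (m)" else "relative index",
              sum(!x$valid)))
  invisible(x)
}

#' Calibrate a relative depth map against survey depths
#'
#' Fits depth (m) as a least-squares linear function of the relative index
#' using survey records that carry both a depth and pixel coordinates at
#' valid map pixels, then applies the line everywhere. Calibrated depths
#' are clamped at 0.
#'
#' @param relmap An uncalibrated `depth_map`.
#' @param table Georeferenced survey data frame with `depth`, `pixel_x`,
#'   `pixel_y`.
#' @return A calibrated `depth_map`; the fitted line is stored in
#'   `$calibration` (`intercept`, `slope`, `n`, `rmse`).
#' @export
calibrate_depth <- function(relmap, table) {
  stopifnot(inherits(relmap, "depth_map"))
  use <- !is.na(table$depth) & !is.na(table$pixel_x) & !is.na(table$pixel_y)
  tab <- table[use, , drop = FALSE]
  idx <- rep(NA_real_, nrow(tab))
  inb <- tab$pixel_y >= 0 & tab$pixel_y < nrow(relmap$values) &
    tab$pixel_x >= 0 & tab$pixel_x < ncol(relmap$values)
  idx[inb] <- relmap$values[cbind(tab$pixel_y[inb] + 1L,
                                  tab$pixel_x[inb] + 1L)]
  ok <- is.finite(idx)
  if (sum(ok) < 2) {
    stop("depth calibration needs >= 2 survey points with depth at valid pixels",
         call. = FALSE)
  }
  if (diff(range(idx[ok])) < .Machine$double.eps * 100) {
    stop("degenerate calibration: all relative indices equal", call. = FALSE)
  }
  fit <- stats::lm(tab$depth[ok] ~ idx[ok])
  coefs <- unname(stats::coef(fit))
  relmap$values <- pmax(coefs[1] + coefs[2] * relmap$values, 0)
  relmap$calibrated <- TRUE
  relmap$calibration <- list(intercept = coefs[1], slope = coefs[2],
                             n = sum(ok),
                             rmse = sqrt(mean(stats::resid(fit)^2)))
  relmap
}

#' Correct reflectance for water-column variance
#'
#' Per pixel, the fitted quadratic gives the percent variance `y` due to
#' the water column; the spectrum is rescaled by `1/(1 - y/100)` (the
#' variance share removed) and re-clipped to [0, 1]. `x` is the natural log
#' of the green/blue reflectance ratio at the model's reference bands,
#' computed from the cube itself when not supplied. Pixels with `y >= cap`
#' are capped and flagged.
#'
#' @param cube A reflectance `spectral_cube`.
#' @param x Optional per-pixel matrix of log-transformed green/blue ratios
#'   aligned to the cube.
#' @param model A `water_column_model`.
#' @param cap Upper cap on `y` (percent, < 100).
#' @return The corrected reflectance cube; attribute `"capped"` holds a
#'   logical matrix of capped pixels.
#' @export
depth_correct <- function(cube, x = NULL, model = water_column_model(),
                          cap = 99) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance") {
    stop("depth correction requires a reflectance cube", call. = FALSE)
  }
  d <- dim(cube$values)
  if (is.null(x)) {
    rb <- band_slice(cube, model$blue_nm)
    rg <- band_slice(cube, model$green_nm)
    x <- matrix(NA_real_, d[1], d[2])
    ok <- rb > 0 & rg > 0
    x[ok] <- log(rg[ok] / rb[ok])
  }
  if (!all(dim(x) == d[1:2])) {
    stop("correction map not aligned to cube", call. = FALSE)
  }
  y <- water_column_variance(x, model)
  y[is.na(y)] <- 0
  capped <- y >= cap
  y[capped] <- cap
  scale <- 1 / (1 - y / 100)
  cube$values <- cube$values * array(rep(scale, d[3]), d)
  cube$values[] <- pmin(pmax(cube$values, 0), 1)
  attr(cube, "capped") <- capped
  cube
}
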