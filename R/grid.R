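#' Build a uniform wavelength grid
#'
#' Band centers of a push-broom VNIR imaging spectrometer are modelled as a
#' uniformly spaced grid. The default sensor configuration used throughout
#' the package is 274 bands over 400--1000 nm, i.e. a ~2.2 nm interval.
#'
#' @param n_bands Number of spectral bands (>= 2).
#' @param lambda_min First band center, nm.
#' @param lambda_max Last band center, nm; must exceed `lambda_min`.
#' @return Numeric vector of strictly increasing band centers (nm) with
#'   class `wavelength_grid`.
#' @examples
#' g <- make_wavelength_grid(274, 400, 1000)
#' diff(g)[1]  # ~2.198 nm
#' @export
make_wavelength_grid <- function(n_bands, lambda_min, lambda_max) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 2 ||
      n_bands != round(n_bands)) {
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.finite(lambda_min) || !is.finite(lambda_max) ||
      lambda_min >= lambda_max) {
    stop("require `lambda_min` < `lambda_max`", call. = FALSE)
  }
  g <- seq(lambda_min, lambda_max, length.out = n_bands)
  structure(g, class = "wavelength_grid")
}

#' Index of the grid band nearest a target wavelength
#'
#' Index wavelengths (e.g. the 575/604 nm pair of an Acropora bleaching
#' index) rarely coincide with the sensor's band centers; the nearest band
#' is substituted. Ties are broken toward the lower band index.
#'
#' @param grid Wavelength grid (numeric, nm).
#' @param lambda_target Target wavelength, nm.
#' @return 1-based band index.
#' @export
nearest_band <- function(grid, lambda_target) {
  grid <- as.numeric(grid)
  if (length(grid) < 1L) stop("empty wavelength grid", call. = FALSE)
  if (!is.finite(lambda_target)) {
    stop("`lambda_target` must be finite", call. = FALSE)
  }
  spacing <- if (length(grid) > 1L) max(diff(grid)) else 1
  if (lambda_target < min(grid) - spacing ||
      lambda_target > max(grid) + spacing) {
    stop(sprintf("wavelength %.1f nm outside grid range [%.1f, %.1f] nm",
                 lambda_target, min(grid), max(grid)), call. = FALSE)
  }
  d <- abs(grid - lambda_target)
  which.min(d)  # which.min returns the first minimum: lower-index tie-break
}
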