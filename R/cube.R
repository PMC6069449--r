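#' Hyperspectral datacube
#'
#' A georeferenced lines x samples x bands raster with its wavelength grid
#' and radiometric kind. Radiance cubes carry sensor units; reflectance
#' cubes are unitless in [0, 1].
#'
#' @param values 3-D numeric array, `rows x cols x bands`.
#' @param wavelength Band centers (nm), length = `dim(values)[3]`.
#' @param gt A `geo_transform` (or `NULL` for an un-georeferenced cube).
#' @param kind `"radiance"` or `"reflectance"`.
#' @return Object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelength, gt = NULL,
                          kind = c("radiance", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a rows x cols x bands array", call. = FALSE)
  }
  wavelength <- as.numeric(wavelength)
  if (dim(values)[3] != length(wavelength)) {
    stop("bands dimension does not match wavelength grid length",
         call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (!is.null(gt)) stopifnot(inherits(gt, "geo_transform"))
  if (kind == "reflectance") {
    values[] <- pmin(pmax(values, 0), 1)
  }
  structure(list(values = values, wavelength = wavelength, gt = gt,
                 kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength), x$kind))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

# pixels as an (rows*cols) x bands matrix, row-major pixel order
cube_to_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, d[1] * d[2], d[3])
}

matrix_to_cube <- function(m, template) {
  d <- dim(template$values)
  template$values <- array(m, d)
  template
}

#' Extract one pixel's spectrum
#'
#' @param cube A `spectral_cube`.
#' @param row,col 0-based pixel coordinates.
#' @return Numeric vector, one value per band.
#' @export
pixel_spectrum <- function(cube, row, col) {
  d <- dim(cube$values)
  if (row < 0 || row >= d[1] || col < 0 || col >= d[2]) {
    stop("pixel outside raster", call. = FALSE)
  }
  as.numeric(cube$values[row + 1L, col + 1L, ])
}
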