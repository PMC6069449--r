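#' Convert a radiance cube to reflectance with a white reference
#'
#' Per pixel and band, reflectance = radiance / white-reference radiance,
#' clipped to [0, 1]. The white reference is the radiance of a
#' unit-reflectance panel under the scene illumination and must be strictly
#' positive in every band. Super-unity ratios (e.g. glint) are clipped.
#'
#' @param cube A radiance `spectral_cube`.
#' @param white Numeric white-reference spectrum, one strictly positive
#'   value per band.
#' @return A reflectance `spectral_cube` on the same grid and geotransform.
#' @export
to_reflectance <- function(cube, white) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "radiance") {
    stop("`cube` is already reflectance", call. = FALSE)
  }
  white <- as.numeric(white)
  if (length(white) != length(cube$wavelength)) {
    stop("white reference length does not match cube bands", call. = FALSE)
  }
  if (any(!is.finite(white)) || any(white <= 0)) {
    stop("invalid white reference: must be strictly positive in every band",
         call. = FALSE)
  }
  d <- dim(cube$values)
  refl <- sweep(cube$values, 3, white, "/")
  spectral_cube(pmin(pmax(refl, 0), 1), cube$wavelength, cube$gt,
                "reflectance")
}

#' Brighten a reflectance cube by a gamma adjustment
#'
#' Classification accuracy on dim underwater scenes can benefit from a
#' bounded brightening before training; a gamma increase of `g` maps each
#' reflectance value `v` to `v^(1/(1+g))`, which preserves [0, 1], fixes 0
#' and 1, and is strictly monotone. The increase is capped at 0.75 (75%).
#' Off by default in the pipeline.
#'
#' @param cube A reflectance `spectral_cube`.
#' @param gamma_increase Fraction in [0, 0.75].
#' @return The adjusted reflectance cube.
#' @export
gamma_adjust <- function(cube, gamma_increase) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance") {
    stop("gamma adjustment applies to reflectance cubes", call. = FALSE)
  }
  if (!is.finite(gamma_increase) || gamma_increase < 0 ||
      gamma_increase > 0.75) {
    stop("`gamma_increase` must lie in [0, 0.75]", call. = FALSE)
  }
  if (gamma_increase == 0) return(cube)
  cube$values[] <- cube$values^(1 / (1 + gamma_increase))
  cube
}

#' Read or write a white-reference spectrum CSV
#'
#' Two columns: wavelength (nm) and panel radiance.
#'
#' @param white Numeric radiance spectrum.
#' @param wavelength Band centers (nm).
#' @param path CSV path.
#' @export
write_white_reference <- function(white, wavelength, path) {
  utils::write.csv(data.frame(wavelength_nm = as.numeric(wavelength),
                              radiance = as.numeric(white)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_white_reference
#' @export
read_white_reference <- function(path) {
  df <- utils::read.csv(path)
  list(wavelength = df[[1]], white = df[[2]])
}
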