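#' Affine geotransform between pixel and geographic coordinates
#'
#' Maps 0-based `(row, col)` pixel coordinates (pixel centers at integer
#' coordinates) to `(lat, lon)` via `c(lat, lon) = origin + A %*% c(row, col)`.
#' Scenes use a local planar approximation; no datum or projection handling.
#'
#' @param origin Length-2 numeric, `(lat, lon)` of pixel `(0, 0)`.
#' @param A 2x2 matrix; row 1 gives d(lat)/d(row), d(lat)/d(col), row 2 the
#'   same for lon. Must be invertible.
#' @return Object of class `geo_transform`.
#' @export
geo_transform <- function(origin, A) {
  A <- matrix(as.numeric(A), 2, 2)
  if (!all(is.finite(A)) || !all(is.finite(origin)) || length(origin) != 2L) {
    stop("invalid geotransform components", call. = FALSE)
  }
  if (abs(det(A)) < .Machine$double.eps * 100) {
    stop("singular geotransform: linear part is not invertible", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), A = A), class = "geo_transform")
}

#' North-up geotransform from an origin and pixel size
#'
#' Convenience constructor: latitude decreases with row, longitude increases
#' with column.
#'
#' @param lat0,lon0 Geographic coordinates of pixel (0, 0).
#' @param res_lat,res_lon Pixel size in degrees (positive).
#' @export
north_up_transform <- function(lat0, lon0, res_lat = 1e-5, res_lon = res_lat) {
  geo_transform(c(lat0, lon0), matrix(c(-res_lat, 0, 0, res_lon), 2, 2,
                                      byrow = TRUE))
}

#' @rdname geo_to_pixel
#' @export
pixel_to_geo <- function(gt, row, col) {
  stopifnot(inherits(gt, "geo_transform"))
  rc <- rbind(as.numeric(row), as.numeric(col))
  out <- gt$origin + gt$A %*% rc
  list(lat = out[1, ], lon = out[2, ])
}

#' Convert between geographic and pixel coordinates
#'
#' `geo_to_pixel` inverts the affine transform and rounds to the nearest
#' integer pixel, with ties (fraction exactly 0.5) broken toward negative
#' infinity, so that `geo_to_pixel(gt, pixel_to_geo(gt, r, c))` is the
#' identity on integer pixels.
#'
#' @param gt A `geo_transform`.
#' @param lat,lon Geographic coordinates (vectors allowed).
#' @param row,col 0-based pixel coordinates.
#' @return `geo_to_pixel`: list with integer `row`, `col`; `pixel_to_geo`:
#'   list with `lat`, `lon`.
#' @export
geo_to_pixel <- function(gt, lat, lon) {
  stopifnot(inherits(gt, "geo_transform"))
  d <- rbind(as.numeric(lat) - gt$origin[1], as.numeric(lon) - gt$origin[2])
  rc <- solve(gt$A, d)
  # round half toward -Inf: ceiling(x - 0.5)
  list(row = as.integer(ceiling(rc[1, ] - 0.5)),
       col = as.integer(ceiling(rc[2, ] - 0.5)))
}
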