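#' Fill pixel coordinates for survey records
#'
#' Maps each record's latitude/longitude to pixel coordinates through the
#' scene geotransform. Records falling outside the raster are flagged in a
#' logical `out_of_bounds` column, never dropped.
#'
#' @param table Survey data frame with `latitude`, `longitude`.
#' @param gt A `geo_transform`.
#' @param shape Optional `c(rows, cols)` for bounds checking.
#' @return The table with `pixel_x`, `pixel_y` filled (and `out_of_bounds`
#'   when `shape` is given).
#' @export
georeference_survey <- function(table, gt, shape = NULL) {
  stopifnot(inherits(gt, "geo_transform"))
  if (nrow(table)) {
    px <- geo_to_pixel(gt, table$latitude, table$longitude)
    table$pixel_x <- px$col
    table$pixel_y <- px$row
  }
  if (!is.null(shape)) {
    table$out_of_bounds <- if (nrow(table)) {
      table$pixel_y < 0 | table$pixel_y >= shape[1] |
        table$pixel_x < 0 | table$pixel_x >= shape[2]
    } else {
      logical(0)
    }
  }
  table
}

signature_set <- function(sigs) structure(sigs, class = "signature_set")

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d classes\n", length(x)))
  for (s in x) cat(sprintf("  %-28s n_pixels = %d\n", s$class, s$n_pixels))
  invisible(x)
}

#' Extract mean spectral signatures per (genus, level) class
#'
#' For each (genus, bleaching level) group in a georeferenced survey table,
#' averages all valid pixels inside a square window centred on each of the
#' group's records. The default 3x3 window absorbs georeferencing jitter.
#' Groups with no valid in-raster pixel are omitted with a warning.
#'
#' @param cube A reflectance `spectral_cube`.
#' @param table Georeferenced survey data frame.
#' @param window Odd window width in pixels (>= 1).
#' @return A `signature_set`: list of signatures, each with `class`,
#'   `genus`, `level`, `mean`, `sd` (per band) and `n_pixels`.
#' @export
extract_signatures <- function(cube, table, window = 3) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be an odd width >= 1", call. = FALSE)
  }
  if (!nrow(table)) return(signature_set(list()))
  if (any(is.na(table$pixel_x) | is.na(table$pixel_y))) {
    stop("table must be georeferenced (pixel coordinates filled)",
         call. = FALSE)
  }
  d <- dim(cube$values)
  half <- (window - 1) / 2
  m <- cube_to_matrix(cube)
  key <- paste0(table$coral_type, " lv", table$bleaching_level)
  sigs <- list()
  for (cl in unique(key)) {
    recs <- table[key == cl, , drop = FALSE]
    pix <- integer(0)
    for (i in seq_len(nrow(recs))) {
      rr <- recs$pixel_y[i] + (-half:half)
      cc <- recs$pixel_x[i] + (-half:half)
      rr <- rr[rr >= 0 & rr < d[1]]
      cc <- cc[cc >= 0 & cc < d[2]]
      if (length(rr) && length(cc)) {
        pix <- c(pix, as.integer(outer(rr + 1L, cc * d[1], `+`)))
      }
    }
    if (!length(pix)) {
      warning("no valid pixels for class ", cl, "; omitted")
      next
    }
    spec <- m[pix, , drop = FALSE]
    sdev <- apply(spec, 2, stats::sd)
    sdev[is.na(sdev)] <- 0  # single-pixel group
    sigs[[cl]] <- list(
      class = cl,
      genus = recs$coral_type[1],
      level = recs$bleaching_level[1],
      mean = colMeans(spec),
      sd = sdev,
      n_pixels = length(pix)
    )
  }
  signature_set(sigs)
}

#' Banded-tolerance match score between two signatures
#'
#' The score is the percentage of bands where the two mean spectra agree
#' within `tolerance` times the signature amplitude, where amplitude is the
#' larger of the two spectral ranges (making the score symmetric in its
#' arguments). With a degenerate (flat) pair the threshold collapses to
#' exact per-band equality. This is the package's pluggable definition of
#' the "signature accuracy" column of the accuracy report.
#'
#' @param candidate,reference Signatures (as produced by
#'   [extract_signatures()]) or bare numeric spectra.
#' @param tolerance Fraction of the signature amplitude (default 0.10).
#' @return Percent of matching bands in [0, 100].
#' @export
signature_match_score <- function(candidate, reference, tolerance = 0.10) {
  cm <- if (is.list(candidate)) candidate$mean else as.numeric(candidate)
  rm_ <- if (is.list(reference)) reference$mean else as.numeric(reference)
  if (length(cm) != length(rm_)) {
    stop("signatures are on different grids", call. = FALSE)
  }
  amp <- max(diff(range(cm)), diff(range(rm_)))
  100 * mean(abs(cm - rm_) <= tolerance * amp)
}

#' Bands where two signatures are separable
#'
#' Returns the band indices where the class means differ by at least
#' `min_gap` reflectance units and the gap exceeds the pooled standard
#' deviation `sqrt(sdA^2 + sdB^2)`.
#'
#' @param sigA,sigB Signatures with `mean` and `sd` fields (bare numeric
#'   spectra are treated as having zero sd).
#' @param min_gap Minimum mean gap in reflectance units.
#' @return Integer vector of band indices (possibly empty).
#' @export
separable_bands <- function(sigA, sigB, min_gap = 0.02) {
  ma <- if (is.list(sigA)) sigA$mean else as.numeric(sigA)
  mb <- if (is.list(sigB)) sigB$mean else as.numeric(sigB)
  if (length(ma) != length(mb)) {
    stop("signatures are on different grids", call. = FALSE)
  }
  sa <- if (is.list(sigA) && !is.null(sigA$sd)) sigA$sd else 0 * ma
  sb <- if (is.list(sigB) && !is.null(sigB$sd)) sigB$sd else 0 * mb
  gap <- abs(ma - mb)
  which(gap >= min_gap & gap > sqrt(sa^2 + sb^2))
}

#' Persist a signature set as CSV
#'
#' Wide format: one row per class, one column per wavelength band, plus
#' `n_pixels`. `long = TRUE` writes a long-format table (class, wavelength,
#' mean, sd) convenient for plotting spectral fingerprints.
#'
#' @param sigs A `signature_set`.
#' @param wavelength Band centers (nm).
#' @param path CSV path.
#' @param long Write long format instead of wide.
#' @export
write_signatures_csv <- function(sigs, wavelength, path, long = FALSE) {
  if (long) {
    rows <- do.call(rbind, lapply(sigs, function(s) {
      data.frame(class = s$class, wavelength_nm = as.numeric(wavelength),
                 mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    mat <- do.call(rbind, lapply(sigs, function(s) s$mean))
    df <- data.frame(class = vapply(sigs, function(s) s$class, character(1)),
                     n_pixels = vapply(sigs, function(s) s$n_pixels,
                                       integer(1)),
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- sprintf("%.2f", as.numeric(wavelength))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
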