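#' In-water survey attribute tables
#'
#' Ground-truth records collected by divers: one row per photographed coral
#' specimen with genus, six-level bleaching score (1 = severely bleached,
#' 6 = unbleached), optional depth, geographic coordinates, and (once
#' georeferenced) pixel coordinates. Persisted as comma-delimited UTF-8 CSV
#' with the canonical column headers `Photo ID, Coral Type, Lv Bleached,
#' Bleached, Depth, Notes, Latitude, Longitude, Pixel x, Pixel y`.
#'
#' @name survey_table
NULL

survey_csv_headers <- c("Photo ID", "Coral Type", "Lv Bleached", "Bleached",
                        "Depth", "Notes", "Latitude", "Longitude",
                        "Pixel x", "Pixel y")

survey_internal_names <- c("photo_id", "coral_type", "bleaching_level",
                           "bleached", "depth", "notes", "latitude",
                           "longitude", "pixel_x", "pixel_y")

empty_survey_table <- function() {
  data.frame(photo_id = integer(0), coral_type = character(0),
             bleaching_level = integer(0), bleached = logical(0),
             depth = numeric(0), notes = character(0),
             latitude = numeric(0), longitude = numeric(0),
             pixel_x = integer(0), pixel_y = integer(0),
             stringsAsFactors = FALSE)
}

validate_survey_table <- function(df) {
  lv <- df$bleaching_level
  bad <- which(!is.na(lv) & (lv < 1 | lv > 6 | lv != round(lv)))
  if (length(bad)) {
    stop(sprintf("bleaching level outside 1-6 in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  badd <- which(!is.na(df$depth) & df$depth < 0)
  if (length(badd)) {
    stop(sprintf("negative depth in row(s): %s",
                 paste(badd, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read or write a survey attribute table CSV
#'
#' Header matching is case-insensitive; blank depth or pixel cells become
#' `NA`. A bleaching level outside 1--6 raises a validation error naming
#' the offending row.
#'
#' @param path CSV file path.
#' @param table Survey data frame (internal column names, as returned by
#'   `read_survey_csv` or [make_survey_table()]).
#' @return `read_survey_csv`: a data frame with columns `photo_id`,
#'   `coral_type`, `bleaching_level`, `bleached`, `depth`, `notes`,
#'   `latitude`, `longitude`, `pixel_x`, `pixel_y`.
#' @export
read_survey_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  hdr <- tolower(trimws(names(raw)))
  want <- tolower(survey_csv_headers)
  idx <- match(want, hdr)
  if (anyNA(idx)) {
    stop("survey CSV missing column(s): ",
         paste(survey_csv_headers[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) return(empty_survey_table())
  raw <- raw[, idx, drop = FALSE]
  names(raw) <- survey_internal_names
  num <- function(x) suppressWarnings(as.numeric(ifelse(trimws(x) == "",
                                                        NA, x)))
  df <- data.frame(
    photo_id = as.integer(num(raw$photo_id)),
    coral_type = trimws(raw$coral_type),
    bleaching_level = as.integer(num(raw$bleaching_level)),
    bleached = tolower(trimws(raw$bleached)) %in% c("yes", "true", "1"),
    depth = num(raw$depth),
    notes = raw$notes,
    latitude = num(raw$latitude),
    longitude = num(raw$longitude),
    pixel_x = as.integer(num(raw$pixel_x)),
    pixel_y = as.integer(num(raw$pixel_y)),
    stringsAsFactors = FALSE
  )
  validate_survey_table(df)
}

#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(table, path) {
  validate_survey_table(table)
  out <- table[, survey_internal_names, drop = FALSE]
  out$bleached <- ifelse(out$bleached, "Yes", "No")
  names(out) <- survey_csv_headers
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Rasterize geographic polygons to a pixel mask
#'
#' A pixel is `TRUE` iff its center lies inside any polygon. Polygons are
#' given in the scene's geographic coordinates as data frames (or 2-column
#' matrices) with `lat`, `lon` vertices.
#'
#' @param polygons List of polygons; each a data frame with `lat` and `lon`
#'   columns (or a 2-column lat/lon matrix). An empty list yields an
#'   all-`FALSE` mask.
#' @param gt A `geo_transform`.
#' @param shape Integer `c(rows, cols)`.
#' @return Logical `rows x cols` matrix.
#' @export
rasterize_polygons <- function(polygons, gt, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L)) {
    stop("`shape` must be positive c(rows, cols)", call. = FALSE)
  }
  mask <- matrix(FALSE, shape[1], shape[2])
  if (!length(polygons)) return(mask)
  rows <- rep(seq_len(shape[1]) - 1L, times = shape[2])
  cols <- rep(seq_len(shape[2]) - 1L, each = shape[1])
  geo <- pixel_to_geo(gt, rows, cols)
  pts <- cbind(geo$lat, geo$lon)
  for (poly in polygons) {
    poly <- as.data.frame(poly)
    if (!all(c("lat", "lon") %in% names(poly))) {
      names(poly)[1:2] <- c("lat", "lon")
    }
    bnd <- cbind(poly$lat, poly$lon)
    inside <- mgcv::in.out(bnd, pts)
    mask <- mask | matrix(inside, shape[1], shape[2])
  }
  mask
}
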