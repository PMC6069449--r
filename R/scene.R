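#' Generate a synthetic shallow-reef scene with known ground truth
#'
#' Places one contiguous blob per requested class over a sand background,
#' with a smooth depth gradient spanning exactly `[0, max_depth]`. Identical
#' seeds and parameters reproduce the scene bit for bit.
#'
#' @param shape Integer `c(rows, cols)`, both positive.
#' @param classes Character vector of class labels (coral labels like
#'   `"Acropora lv3"`, or background classes); nonempty. Every requested
#'   class is guaranteed at least one pixel.
#' @param max_depth Maximum water depth (m).
#' @param seed Integer seed.
#' @param library Optional `endmember_library`; by default one is
#'   synthesized (seeded with `seed`) covering the coral classes requested.
#' @param gt Optional `geo_transform`; defaults to a north-up transform
#'   anchored near the package's reference reef site.
#' @return Object of class `scene_truth`: list with `labels` (character
#'   matrix), `depth` (numeric matrix, m), `library`, `gt`, `seed`.
#' @export
make_scene <- function(shape, classes, max_depth = 3, seed = 0,
                       library = NULL, gt = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L)) {
    stop("`shape` must be positive c(rows, cols)", call. = FALSE)
  }
  if (!length(classes)) stop("`classes` must be nonempty", call. = FALSE)
  if (length(classes) > prod(shape)) {
    stop("more classes than pixels", call. = FALSE)
  }
  if (max_depth < 0) stop("`max_depth` must be >= 0", call. = FALSE)
  if (is.null(library)) {
    info <- parse_class_label(classes)
    genera <- unique(stats::na.omit(info$genus))
    if (!length(genera)) genera <- "Acropora"
    library <- synth_endmembers(genera, 1:6, seed = seed)
  }
  known <- colnames(library$spectra)
  unknown <- setdiff(classes, known)
  if (length(unknown)) {
    stop("classes missing from endmember library: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(gt)) gt <- north_up_transform(18.8129, 146.4267, 1e-5)

  rows <- shape[1]; cols <- shape[2]
  labels <- matrix("sand", rows, cols)
  blob_classes <- setdiff(classes, "sand")
  with_seed(seed, {
    r_blob <- max(2L, as.integer(floor(min(shape) * 0.11)))
    centers <- matrix(NA_real_, 0, 2)
    for (cl in blob_classes) {
      best <- NULL
      for (try in 1:60) {
        cand <- c(stats::runif(1, r_blob, rows - 1 - r_blob),
                  stats::runif(1, r_blob, cols - 1 - r_blob))
        if (rows - 1 <= 2 * r_blob) cand[1] <- stats::runif(1, 0, rows - 1)
        if (cols - 1 <= 2 * r_blob) cand[2] <- stats::runif(1, 0, cols - 1)
        if (!nrow(centers) ||
            min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                               byrow = TRUE))^2))) >
            2.2 * r_blob) {
          best <- cand
          break
        }
        best <- cand  # fallback: last candidate, overlap allowed
      }
      centers <- rbind(centers, best)
      rr <- outer(seq_len(rows) - 1, rep(1, cols)) - best[1]
      cc <- outer(rep(1, rows), seq_len(cols) - 1) - best[2]
      # slightly irregular blob edge
      wob <- 1 + 0.15 * sin(3 * atan2(cc, rr) + stats::runif(1, 0, 2 * pi))
      labels[sqrt(rr^2 + cc^2) <= r_blob * wob] <- cl
    }
    # guarantee every requested class at least one pixel
    for (i in seq_along(blob_classes)) {
      if (!any(labels == blob_classes[i])) {
        rc <- round(centers[i, ]) + 1
        labels[rc[1], rc[2]] <- blob_classes[i]
      }
    }
    phase <- stats::runif(1, 0, 2 * pi)
    raw <- outer(seq_len(rows) - 1, rep(1, cols)) / max(rows - 1, 1) +
      0.08 * sin(2 * pi * (outer(rep(1, rows), seq_len(cols) - 1) /
                             max(cols - 1, 1)) + phase)
    depth <- if (diff(range(raw)) > 0) {
      max_depth * (raw - min(raw)) / diff(range(raw))
    } else {
      raw * 0
    }
  })
  structure(list(labels = labels, depth = depth, library = library,
                 gt = gt, seed = seed),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d pixels, %d classes, depth %.2f-%.2f m\n",
              nrow(x$labels), ncol(x$labels), length(unique(c(x$labels))),
              min(x$depth), max(x$depth)))
  invisible(x)
}

default_illumination <- function(grid) {
  g <- as.numeric(grid)
  800 + 600 * exp(-((g - 560) / 260)^2)
}

#' Render a scene to a radiance cube plus white reference
#'
#' Forward model: per pixel, the observed above-water reflectance is
#' `R_obs(lambda) = R_bottom(lambda) * exp(-2 k(lambda) z) + offset(lambda)`
#' (two-way Beer--Lambert attenuation through depth `z` plus water-leaving
#' offset), scaled by the illumination spectrum into radiance, with
#' i.i.d. zero-mean Gaussian noise (reflectance units) added per band per
#' pixel. The returned white reference is the radiance of a unit-reflectance
#' panel, i.e. the illumination spectrum itself.
#'
#' @param truth A `scene_truth`.
#' @param water A `water_model` on the same wavelength grid.
#' @param illumination Per-band radiance of a unit-reflectance panel;
#'   default a smooth solar-like curve.
#' @param noise_sd Gaussian noise standard deviation in reflectance units
#'   (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return List with `cube` (radiance `spectral_cube`) and `white`
#'   (numeric white-reference spectrum).
#' @export
render_cube <- function(truth, water, illumination = NULL, noise_sd = 0,
                        seed = 0) {
  stopifnot(inherits(truth, "scene_truth"), inherits(water, "water_model"))
  wl <- truth$library$wavelength
  if (length(wl) != length(water$wavelength) ||
      any(abs(wl - water$wavelength) > 1e-9)) {
    stop("scene and water model wavelength grids differ", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(illumination)) illumination <- default_illumination(wl)
  if (length(illumination) != length(wl) || any(illumination <= 0)) {
    stop("illumination must be positive with one value per band",
         call. = FALSE)
  }
  d <- c(dim(truth$labels), length(wl))
  lab <- as.character(truth$labels)
  idx <- match(lab, colnames(truth$library$spectra))
  r_bottom <- t(truth$library$spectra[, idx, drop = FALSE])   # npix x bands
  att <- exp(-2 * outer(as.numeric(truth$depth), water$k))    # npix x bands
  r_obs <- r_bottom * att + matrix(water$offset, nrow(att), d[3],
                                   byrow = TRUE)
  if (noise_sd > 0) {
    with_seed(seed, {
      r_obs <- r_obs + matrix(stats::rnorm(length(r_obs), 0, noise_sd),
                              nrow(r_obs), ncol(r_obs))
    })
  }
  rad <- r_obs * matrix(illumination, nrow(r_obs), d[3], byrow = TRUE)
  rad <- pmax(rad, 0)
  cube <- spectral_cube(array(rad, d), wl, truth$gt, "radiance")
  list(cube = cube, white = illumination)
}

#' Sample an in-water survey table from scene truth
#'
#' Draws `n_points` records from coral pixels with correct genus, level,
#' depth and geographic coordinates. Sampling is lightly stratified: every
#' coral class present receives at least two points where availability and
#' `n_points` allow (an in-water survey records each class it encounters),
#' with the remainder drawn uniformly without replacement.
#'
#' @param truth A `scene_truth`.
#' @param n_points Number of records (0 allowed; must not exceed the number
#'   of coral pixels).
#' @param seed Integer seed.
#' @return Survey data frame (see [read_survey_csv()] for columns).
#' @export
make_survey_table <- function(truth, n_points = 64, seed = 0) {
  stopifnot(inherits(truth, "scene_truth"))
  coral <- which(is_coral_label(truth$labels))
  if (!length(coral)) stop("scene contains no coral pixels", call. = FALSE)
  if (n_points > length(coral)) {
    stop("`n_points` exceeds the number of coral pixels", call. = FALSE)
  }
  if (n_points == 0L) return(empty_survey_table())
  labs <- truth$labels[coral]
  picked <- integer(0)
  with_seed(seed, {
    classes <- unique(labs)
    quota <- 2L
    if (length(classes) * quota > n_points) quota <- 1L
    if (length(classes) * quota > n_points) quota <- 0L
    for (cl in classes) {
      pool <- coral[labs == cl]
      take <- min(quota, length(pool))
      if (take > 0) picked <- c(picked, sample(pool, take))
    }
    rest <- setdiff(coral, picked)
    extra <- n_points - length(picked)
    if (extra > 0) picked <- c(picked, sample(rest, extra))
  })
  picked <- picked[seq_len(n_points)]
  rows <- (picked - 1L) %% nrow(truth$labels)         # 0-based
  cols <- (picked - 1L) %/% nrow(truth$labels)
  info <- parse_class_label(truth$labels[picked])
  geo <- pixel_to_geo(truth$gt, rows, cols)
  df <- data.frame(
    photo_id = seq_len(n_points),
    coral_type = info$genus,
    bleaching_level = info$level,
    bleached = info$level <= 2,
    depth = round(truth$depth[picked], 2),
    notes = "",
    latitude = geo$lat,
    longitude = geo$lon,
    pixel_x = as.integer(cols),
    pixel_y = as.integer(rows),
    stringsAsFactors = FALSE
  )
  validate_survey_table(df)
}

#' Overlay spume (sea foam) polygons on a scene
#'
#' Pixels whose centers fall inside any polygon are relabelled `"spume"`,
#' which carries a bright flat reflectance in the endmember library. A
#' polygon covering no pixel center triggers a warning and changes nothing.
#'
#' @param truth A `scene_truth`.
#' @param polygons List of polygons in scene geographic coordinates (see
#'   [rasterize_polygons()]).
#' @return The modified `scene_truth`.
#' @export
add_spume <- function(truth, polygons) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!length(polygons)) return(truth)
  for (i in seq_along(polygons)) {
    m <- rasterize_polygons(polygons[i], truth$gt, dim(truth$labels))
    if (!any(m)) {
      warning(sprintf("spume polygon %d covers no pixel center; ignored", i))
    }
    truth$labels[m] <- "spume"
  }
  truth
}
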