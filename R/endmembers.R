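# Synthetic endmember spectra for shallow-reef scenes.
#
# No public numeric library of coral bleaching spectra exists for the study
# design this package supports, so endmembers are synthetic smooth curves
# built to honour the field's qualitative contracts: per genus, band-mean
# reflectance strictly decreases from bleaching level 1 (severely bleached,
# whitest) to level 6 (healthy), and bleached spectra are elevated near
# 400 nm and 750 nm relative to unbleached ones.

with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# smooth interpolation of anchor points onto a grid, clipped to [0, 1]
anchor_spectrum <- function(grid, anchors_nm, anchors_r) {
  s <- stats::spline(anchors_nm, anchors_r, xout = as.numeric(grid),
                     method = "natural")$y
  pmin(pmax(s, 0), 1)
}

# fully pigmented (healthy) coral shape: strong green/blue contrast
# (R540/R480 ~ 2.1) and a modest near-infrared red edge
pigment_shape <- function(grid) {
  anchor_spectrum(grid,
    c(395, 420, 450, 480, 510, 540, 560, 600, 650, 680, 700, 730, 760, 850,
      1000),
    c(0.050, 0.058, 0.070, 0.080, 0.120, 0.170, 0.180, 0.160, 0.140, 0.120,
      0.200, 0.270, 0.310, 0.320, 0.290))
}

# bare bleached skeleton: bright, with local elevation near 400 and 750 nm
bleached_shape <- function(grid) {
  base <- anchor_spectrum(grid,
    c(395, 430, 470, 520, 570, 620, 670, 710, 760, 850, 1000),
    c(0.70, 0.66, 0.63, 0.62, 0.63, 0.62, 0.62, 0.65, 0.70, 0.67, 0.62))
  g <- as.numeric(grid)
  bump <- 0.06 * exp(-((g - 400) / 22)^2) + 0.05 * exp(-((g - 750) / 30)^2)
  pmin(base + bump, 1)
}

sand_shape <- function(grid) {
  anchor_spectrum(grid,
    c(395, 450, 480, 540, 600, 700, 800, 1000),
    c(0.22, 0.27, 0.30, 0.35, 0.38, 0.42, 0.45, 0.48))
}

# dark benthic cover: sand shape dimmed by a spectrally flat factor, so the
# bright-sand vs dark-bottom contrast is a pure brightness (albedo) change
benthos_shape <- function(grid) 0.40 * sand_shape(grid)

water_shape <- function(grid) {
  anchor_spectrum(grid, c(395, 500, 600, 1000), c(0.030, 0.020, 0.008, 0.004))
}

spume_reflectance <- 0.90

#' Class label helpers
#'
#' Coral classes are keyed jointly by genus and bleaching level and labelled
#' `"<genus> lv<level>"`; background classes are `"sand"`, `"benthos"`,
#' `"water"` and `"spume"`.
#'
#' @param genus Genus name (free text).
#' @param level Bleaching level 1--6.
#' @export
coral_class_label <- function(genus, level) paste0(genus, " lv", level)

#' @rdname coral_class_label
#' @param label Class label(s).
#' @export
is_coral_label <- function(label) grepl(" lv[1-6]$", label)

#' @rdname coral_class_label
#' @export
parse_class_label <- function(label) {
  m <- regmatches(label, regexec("^(.*) lv([1-6])$", label))
  genus <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                  character(1))
  level <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else
    NA_integer_, integer(1))
  data.frame(genus = genus, level = level, stringsAsFactors = FALSE)
}

#' Synthesize an endmember library
#'
#' Builds one reflectance spectrum per (genus, bleaching level) class plus
#' the `sand`, `benthos`, `water` and `spume` background classes. Each coral
#' spectrum is a convex mix of a bright bleached-skeleton shape and a
#' genus-specific pigmented shape, with mixing weight `(6 - level)/5`, so
#' band-mean brightness is strictly decreasing over levels 1 to 6 and
#' heavily bleached levels are elevated near 400 nm and 750 nm. A small
#' seeded smooth perturbation differentiates genera.
#'
#' @param genera Character vector of genus names (nonempty).
#' @param levels Integer bleaching levels, subset of 1:6.
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param grid Wavelength grid (defaults to the 274-band 400--1000 nm
#'   sensor grid).
#' @return Object of class `endmember_library`: list with `wavelength` and
#'   `spectra` (bands x classes matrix with class-label column names).
#' @export
synth_endmembers <- function(genera, levels = 1:6, seed = 1,
                             grid = make_wavelength_grid(274, 400, 1000)) {
  if (!length(genera)) stop("`genera` must be nonempty", call. = FALSE)
  levels <- as.integer(levels)
  if (!length(levels) || !all(levels %in% 1:6)) {
    stop("`levels` must be a subset of 1:6", call. = FALSE)
  }
  g <- as.numeric(grid)
  bleach <- bleached_shape(grid)
  spectra <- list()
  with_seed(seed, {
    for (gen in genera) {
      # smooth multiplicative wiggle, +/- ~5%, keeps blue-green contrast
      centers <- stats::runif(3, 430, 950)
      amps <- stats::runif(3, -0.05, 0.05)
      wig <- 1 + Reduce(`+`, lapply(1:3, function(i)
        amps[i] * exp(-((g - centers[i]) / 60)^2)))
      pig <- pmin(pmax(pigment_shape(grid) * wig, 0.01), 1)
      for (lv in sort(levels)) {
        w <- (6 - lv) / 5
        spectra[[coral_class_label(gen, lv)]] <- w * bleach + (1 - w) * pig
      }
    }
  })
  spectra[["sand"]] <- sand_shape(grid)
  spectra[["benthos"]] <- benthos_shape(grid)
  spectra[["water"]] <- water_shape(grid)
  spectra[["spume"]] <- rep(spume_reflectance, length(g))
  mat <- do.call(cbind, spectra)
  structure(list(wavelength = g, spectra = mat), class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("<endmember_library> %d classes x %d bands\n",
              ncol(x$spectra), nrow(x$spectra)))
  invisible(x)
}

library_spectrum <- function(lib, label) {
  if (!label %in% colnames(lib$spectra)) {
    stop("class not in endmember library: ", label, call. = FALSE)
  }
  as.numeric(lib$spectra[, label])
}

#' Shallow-water optical model
#'
#' Two-way Beer--Lambert attenuation with a small water-leaving offset:
#' the water column multiplies bottom reflectance by `exp(-2 k(lambda) z)`
#' and adds `offset(lambda)`. The diffuse attenuation curve `k(lambda)` is
#' low in the blue, higher in the green (a requirement for the blue/green
#' log-ratio depth index to be monotone in depth), and rises steeply in the
#' near infrared, which realistically extinguishes NIR signal at depth.
#'
#' @param grid Wavelength grid (nm).
#' @param k_scale Multiplier on the default attenuation curve (1/m).
#' @param offset_scale Multiplier on the default water-leaving offset.
#' @param max_depth Maximum depth the model is intended for (m).
#' @param blue_nm,green_nm Reference wavelengths for the depth log-ratio.
#' @return Object of class `water_model` with per-band `k` (1/m), `offset`,
#'   and the reference wavelengths.
#' @export
make_water_model <- function(grid, k_scale = 1, offset_scale = 1,
                             max_depth = 8, blue_nm = 480, green_nm = 540) {
  g <- as.numeric(grid)
  k <- anchor_spectrum(grid,
    c(395, 450, 480, 520, 540, 560, 600, 650, 700, 730, 750, 780, 800, 850,
      900, 950, 1000),
    c(0.085, 0.090, 0.100, 0.150, 0.200, 0.220, 0.280, 0.360, 0.650, 1.90,
      2.85, 2.70, 2.25, 4.30, 6.50, 25.0, 30.0) / 30) * 30 * k_scale
  offset <- anchor_spectrum(grid,
    c(395, 500, 600, 700, 1000),
    c(0.004, 0.0025, 0.0010, 0.0005, 0.0003)) * offset_scale
  if (blue_nm >= green_nm) stop("blue reference must be below green",
                                call. = FALSE)
  kb <- k[nearest_band(g, blue_nm)]
  kg <- k[nearest_band(g, green_nm)]
  if (!(kg > kb)) stop("water model requires k(green) > k(blue)",
                       call. = FALSE)
  structure(list(wavelength = g, k = pmax(k, 0), offset = pmax(offset, 0),
                 max_depth = max_depth, blue_nm = blue_nm,
                 green_nm = green_nm),
            class = "water_model")
}
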