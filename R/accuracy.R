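# Thematic-map accuracy assessment: per-(genus, level) rows combining a
# signature match score, point-detection accuracy at survey locations,
# mapped-area fractions with excessive-area (EA) flagging, and the overall
# combination rule. The report layout mirrors the field convention:
# Coral Type | Bleaching Level | Signature Accuracy (%) | Points Found |
# Accuracy (%) | Found Pixels | Area (%) | Overall Accuracy (%).

trunc3 <- function(x) floor(x * 1000 + 1e-9) / 1000

#' Point-detection accuracy
#'
#' `100 * found / total`, reported to 3 decimals (truncated, the convention
#' the report's printed ratios follow, e.g. 3/14 -> 21.428).
#'
#' @param found,total Counts with `0 <= found <= total`, `total >= 1`.
#' @return Percent in [0, 100].
#' @export
point_detection_accuracy <- function(found, total) {
  if (any(total < 1)) stop("`total` must be >= 1", call. = FALSE)
  if (any(found < 0 | found > total)) {
    stop("require 0 <= found <= total", call. = FALSE)
  }
  trunc3(100 * found / total)
}

#' Mapped pixel count and area fraction of a class
#'
#' Counts the class's pixels among non-excluded pixels, and expresses the
#' count as a percentage of the full scene pixel count.
#'
#' @param cmap A `class_map`.
#' @param label Class label present in the legend.
#' @return List with `found_pixels` and `area_percent`.
#' @export
mapped_area_fraction <- function(cmap, label) {
  stopifnot(inherits(cmap, "class_map"))
  id <- match(label, cmap$legend)
  if (is.na(id)) stop("class not in legend: ", label, call. = FALSE)
  n <- sum(cmap$ids == id & cmap$valid, na.rm = TRUE)
  list(found_pixels = n, area_percent = 100 * n / length(cmap$ids))
}

#' Excessive-area (EA) flag
#'
#' A class is flagged EA when its mapped area strictly exceeds `factor`
#' times its reference prevalence (from scene truth when available, else
#' user supplied). A nonzero area against zero reference prevalence is
#' flagged with a warning.
#'
#' @param area_percent Mapped area, percent of scene.
#' @param reference_prevalence Reference prevalence, percent of scene.
#' @param factor Multiplier (> 1), default 5.
#' @return Logical.
#' @export
excessive_area_flag <- function(area_percent, reference_prevalence,
                                factor = 5) {
  if (area_percent < 0 || reference_prevalence < 0) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  if (factor <= 1) stop("`factor` must be > 1", call. = FALSE)
  if (reference_prevalence == 0 && area_percent > 0) {
    warning("nonzero mapped area with zero reference prevalence")
    return(TRUE)
  }
  area_percent > factor * reference_prevalence
}

#' Overall accuracy combination rule
#'
#' 0 when the class is EA-flagged, otherwise the minimum of the signature
#' accuracy and the point-detection accuracy. This rule reproduces every
#' printed overall-accuracy cell of the reference report layout.
#'
#' @param signature_accuracy,points_accuracy Percents in [0, 100].
#' @param ea_flag Logical EA flag.
#' @return Percent in [0, 100].
#' @export
overall_accuracy <- function(signature_accuracy, points_accuracy, ea_flag) {
  if (any(c(signature_accuracy, points_accuracy) < 0) ||
      any(c(signature_accuracy, points_accuracy) > 100)) {
    stop("accuracies must lie in [0, 100]", call. = FALSE)
  }
  ifelse(ea_flag, 0, pmin(signature_accuracy, points_accuracy))
}

# is the record's class present in the map within a (2h+1)^2 window?
point_found <- function(cmap, row, col, id, half = 1) {
  d <- dim(cmap$ids)
  rr <- (row - half):(row + half)
  cc <- (col - half):(col + half)
  rr <- rr[rr >= 0 & rr < d[1]]
  cc <- cc[cc >= 0 & cc < d[2]]
  if (!length(rr) || !length(cc)) return(FALSE)
  any(cmap$ids[rr + 1L, cc + 1L, drop = FALSE] == id &
        cmap$valid[rr + 1L, cc + 1L, drop = FALSE], na.rm = TRUE)
}

#' Assemble the accuracy report
#'
#' One row per (genus, bleaching level) present in the survey table. A
#' survey point counts as "found" when the class map contains its class
#' within a tolerance window around its pixel (default 3x3). Survey
#' classes missing from the map legend are listed in the `footer`
#' attribute, never silently dropped.
#'
#' @param cmap A `class_map`.
#' @param table Georeferenced survey data frame.
#' @param sigs Extracted `signature_set` (candidates).
#' @param refs Reference `signature_set` keyed by the same class labels.
#' @param prevalence Named numeric vector of reference prevalences
#'   (percent of scene) per class label, e.g. from scene truth. Classes
#'   absent from a supplied vector get prevalence 0 (and are flagged when
#'   mapped); with `prevalence = NULL` the EA criterion is not assessable
#'   and no row is flagged.
#' @param ea_factor EA multiplier (> 1).
#' @param tolerance Signature match tolerance (see
#'   [signature_match_score()]).
#' @param window Odd point-matching window width in pixels.
#' @return Data frame of class `accuracy_report` with columns
#'   `coral_type`, `bleaching_level`, `signature_accuracy`, `points_found`,
#'   `points_total`, `points_accuracy`, `found_pixels`, `area_percent`,
#'   `ea_flag`, `overall_accuracy`.
#' @export
build_report <- function(cmap, table, sigs, refs, prevalence = NULL,
                         ea_factor = 5, tolerance = 0.10, window = 3) {
  stopifnot(inherits(cmap, "class_map"))
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be an odd width >= 1", call. = FALSE)
  }
  half <- (window - 1) / 2
  key <- paste0(table$coral_type, " lv", table$bleaching_level)
  classes <- unique(key)
  footer <- setdiff(classes, cmap$legend)
  rows <- list()
  for (cl in classes) {
    recs <- table[key == cl, , drop = FALSE]
    id <- match(cl, cmap$legend)
    if (is.na(id)) next
    found <- sum(vapply(seq_len(nrow(recs)), function(i) {
      point_found(cmap, recs$pixel_y[i], recs$pixel_x[i], id, half)
    }, logical(1)))
    pa <- point_detection_accuracy(found, nrow(recs))
    sig <- if (cl %in% names(sigs) && cl %in% names(refs)) {
      signature_match_score(sigs[[cl]], refs[[cl]], tolerance)
    } else {
      NA_real_
    }
    area <- mapped_area_fraction(cmap, cl)
    ea <- if (is.null(prevalence)) {
      FALSE
    } else {
      prev <- if (cl %in% names(prevalence)) prevalence[[cl]] else 0
      suppressWarnings(
        excessive_area_flag(area$area_percent, prev, ea_factor))
    }
    ov <- if (is.na(sig)) {
      overall_accuracy(pa, pa, ea)
    } else {
      overall_accuracy(sig, pa, ea)
    }
    rows[[cl]] <- data.frame(
      coral_type = recs$coral_type[1],
      bleaching_level = recs$bleaching_level[1],
      signature_accuracy = sig,
      points_found = found,
      points_total = nrow(recs),
      points_accuracy = pa,
      found_pixels = area$found_pixels,
      area_percent = area$area_percent,
      ea_flag = ea,
      overall_accuracy = ov,
      stringsAsFactors = FALSE
    )
  }
  rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(rep)) rep <- data.frame()
  attr(rep, "footer") <- footer
  class(rep) <- c("accuracy_report", class(rep))
  rep
}

#' Write an accuracy report CSV in the canonical column layout
#'
#' Accuracy (%) is printed to 3 decimals, Overall Accuracy (%) to 2, with
#' EA-flagged rows printed as `0 (EA)`.
#'
#' @param report An `accuracy_report`.
#' @param path CSV path.
#' @export
write_report_csv <- function(report, path) {
  out <- data.frame(
    `Coral Type` = report$coral_type,
    `Bleaching Level` = report$bleaching_level,
    `Signature Accuracy (%)` = sprintf("%.2f", report$signature_accuracy),
    `Points Found` = sprintf("%d/%d", report$points_found,
                             report$points_total),
    `Accuracy (%)` = sprintf("%.3f", report$points_accuracy),
    `Found Pixels` = report$found_pixels,
    `Area (%)` = sprintf("%.3f", report$area_percent),
    `Overall Accuracy (%)` = ifelse(report$ea_flag, "0 (EA)",
                                    sprintf("%.2f",
                                            report$overall_accuracy)),
    ea_flag = report$ea_flag,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
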