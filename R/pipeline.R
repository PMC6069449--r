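#' Configuration for an end-to-end pipeline run
#'
#' Collects the inputs and tunables of the workflow: radiance cube + white
#' reference, survey table, optional spume polygons, the water-column model
#' and stretch factor, optional image gamma, denoise windows, SVM
#' hyperparameters, and assessment settings. All randomness funnels through
#' the single `seed`.
#'
#' @param cube Radiance `spectral_cube` (or a path readable by
#'   [read_cube()]).
#' @param white White-reference spectrum (or a 2-column CSV path).
#' @param survey Survey data frame (or a CSV path).
#' @param spume_polygons Optional polygon list for exclusion masking.
#' @param wc_model A `water_column_model`.
#' @param stretch_n Log-ratio stretch factor.
#' @param gamma_increase Optional image gamma increase in [0, 0.75]
#'   (default 0 = off).
#' @param svm_gamma,svm_C SVM hyperparameters (`NULL` gamma = scaled
#'   default).
#' @param spectral_window,spatial_window Denoise windows (odd; 1 = off).
#' @param ea_factor Excessive-area multiplier.
#' @param prevalence Named reference prevalences (percent) per class.
#' @param reference_signatures Optional reference `signature_set` for the
#'   signature-accuracy column (defaults to the extracted signatures,
#'   giving 100%).
#' @param extra_training Optional list with `x` (spectra matrix) and
#'   `labels`, e.g. analyst-picked background regions (sand, benthos).
#' @param sig_window Signature extraction window (odd).
#' @param match_window Point-matching window for the report (odd).
#' @param tolerance Signature match tolerance.
#' @param unsupervised_k Optional cluster count for the unsupervised
#'   refinement flags (`NULL` = skip).
#' @param depth_limit Depth (m) beyond which classification is considered
#'   unreliable; a fully deeper scene triggers a warning.
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
make_pipeline_config <- function(cube, white, survey, spume_polygons = NULL,
                                 wc_model = water_column_model(),
                                 stretch_n = 1000, gamma_increase = 0,
                                 svm_gamma = NULL, svm_C = 10,
                                 spectral_window = 5, spatial_window = 3,
                                 ea_factor = 5, prevalence = NULL,
                                 reference_signatures = NULL,
                                 extra_training = NULL, sig_window = 3,
                                 match_window = 3, tolerance = 0.10,
                                 unsupervised_k = NULL, depth_limit = 8,
                                 seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_inputs <- function(config) {
  if (is.character(config$cube)) config$cube <- read_cube(config$cube)
  if (is.character(config$white)) {
    config$white <- read_white_reference(config$white)$white
  }
  if (is.character(config$survey)) {
    config$survey <- read_survey_csv(config$survey)
  }
  config
}

#' Run the full detection workflow
#'
#' Stages, in order: radiance-to-reflectance conversion, optional gamma
#' adjustment, relative-depth estimation with survey calibration,
#' water-column correction, survey georeferencing and signature
#' extraction, bleaching-index evaluation, spectral/spatial denoising,
#' supervised RBF-SVM classification (trained on survey-pixel spectra plus
#' any supplied background regions), optional unsupervised refinement
#' flags, spume-exclusion masking, and accuracy-report assembly. When
#' spume polygons are supplied the report is produced both without and
#' with the exclusion applied; excluded survey points are also dropped
#' from training in the excluded run.
#'
#' @param config A `pipeline_config`.
#' @return List with `reflectance`, `corrected`, `depth`, `survey`,
#'   `signatures`, `indices`, `model`, `class_map`, `report`, and, when
#'   polygons are present, `exclusion_mask`, `class_map_excluded`,
#'   `report_excluded`; plus `refine_flags` when `unsupervised_k` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- resolve_inputs(config)
  cube <- config$cube
  d <- dim(cube$values)

  refl <- to_reflectance(cube, config$white)
  if (config$gamma_increase > 0) {
    refl <- gamma_adjust(refl, config$gamma_increase)
  }

  survey <- georeference_survey(config$survey, cube$gt, d[1:2])
  relmap <- relative_depth_log_ratio(refl, config$wc_model,
                                     config$stretch_n)
  depth <- tryCatch(calibrate_depth(relmap, survey),
                    error = function(e) relmap)
  if (depth$calibrated && all(is.na(depth$values) |
                              depth$values > config$depth_limit)) {
    warning(sprintf("entire scene deeper than %.1f m: beyond the reliable ",
                    config$depth_limit),
            "classification depth of the band-ratio method")
  }
  corrected <- depth_correct(refl, model = config$wc_model)

  sigs <- extract_signatures(corrected, survey, config$sig_window)
  refs <- if (is.null(config$reference_signatures)) sigs else
    config$reference_signatures
  idx <- evaluate_table1(corrected, strict = FALSE)

  work <- denoise(corrected, config$spectral_window, config$spatial_window)

  train_from <- function(tab) {
    keep <- tab$pixel_y >= 0 & tab$pixel_y < d[1] &
      tab$pixel_x >= 0 & tab$pixel_x < d[2]
    tab <- tab[keep, , drop = FALSE]
    x <- t(vapply(seq_len(nrow(tab)), function(i) {
      pixel_spectrum(work, tab$pixel_y[i], tab$pixel_x[i])
    }, numeric(d[3])))
    labels <- paste0(tab$coral_type, " lv", tab$bleaching_level)
    if (!is.null(config$extra_training)) {
      x <- rbind(x, config$extra_training$x)
      labels <- c(labels, config$extra_training$labels)
    }
    list(x = x, labels = labels)
  }

  tr <- train_from(survey)
  model <- train_classifier(tr$x, tr$labels, config$svm_gamma, config$svm_C)
  cmap <- predict_map(model, work)

  out <- list(reflectance = refl, corrected = corrected, depth = depth,
              survey = survey, signatures = sigs, indices = idx,
              model = model, class_map = cmap)

  if (!is.null(config$unsupervised_k)) {
    ub <- unsupervised_baseline(work, config$unsupervised_k, config$seed)
    out$unsupervised <- ub
    out$refine_flags <- refinement_flags(cmap, ub)
  }

  out$report <- build_report(cmap, survey, sigs, refs, config$prevalence,
                             config$ea_factor, config$tolerance,
                             config$match_window)

  if (!is.null(config$spume_polygons) && length(config$spume_polygons)) {
    mask <- rasterize_polygons(config$spume_polygons, cube$gt, d[1:2])
    survey_ex <- survey[!mask[cbind(survey$pixel_y + 1L,
                                    survey$pixel_x + 1L)], , drop = FALSE]
    tr2 <- train_from(survey_ex)
    model2 <- train_classifier(tr2$x, tr2$labels, config$svm_gamma,
                               config$svm_C)
    cmap2 <- apply_exclusion_mask(predict_map(model2, work), mask)
    sigs2 <- extract_signatures(corrected, survey_ex, config$sig_window)
    refs2 <- if (is.null(config$reference_signatures)) sigs2 else
      config$reference_signatures
    out$exclusion_mask <- mask
    out$class_map_excluded <- cmap2
    out$report_excluded <- build_report(cmap2, survey_ex, sigs2, refs2,
                                        config$prevalence, config$ea_factor,
                                        config$tolerance,
                                        config$match_window)
  }
  out
}

#' Unsupervised refinement flags
#'
#' Flags pixels whose supervised label differs from the majority supervised
#' label of their unsupervised cluster — regions worth reviewing. A review
#' aid only; it never overwrites supervised labels.
#'
#' @param cmap Supervised `class_map`.
#' @param ucmap Unsupervised baseline `class_map` (see
#'   [unsupervised_baseline()]).
#' @return Logical matrix of flagged pixels.
#' @export
refinement_flags <- function(cmap, ucmap) {
  flags <- matrix(FALSE, nrow(cmap$ids), ncol(cmap$ids))
  sup <- cmap$ids
  cl <- ucmap$ids
  ok <- !is.na(sup) & !is.na(cl)
  for (k in unique(cl[ok])) {
    sel <- ok & cl == k
    tab <- tabulate(sup[sel], nbins = length(cmap$legend))
    maj <- which.max(tab)
    flags[sel & sup != maj] <- TRUE
  }
  flags
}

#' Per-class recall of a class map against truth labels
#'
#' Recall of class `c` = correctly labelled pixels / truth pixels of `c`,
#' computed over non-excluded pixels (and outside `mask` when given).
#'
#' @param cmap A `class_map`.
#' @param truth_labels Character matrix of true class labels.
#' @param classes Classes to report (default: map legend).
#' @return Named numeric vector of recalls in [0, 1] (NaN for classes with
#'   no assessable truth pixels).
#' @export
class_recall <- function(cmap, truth_labels, classes = cmap$legend) {
  stopifnot(inherits(cmap, "class_map"))
  pred <- matrix(cmap$legend[cmap$ids], nrow(cmap$ids), ncol(cmap$ids))
  assess <- cmap$valid
  out <- vapply(classes, function(cl) {
    tp <- sum(assess & truth_labels == cl & pred == cl, na.rm = TRUE)
    p <- sum(assess & truth_labels == cl, na.rm = TRUE)
    tp / p
  }, numeric(1))
  names(out) <- classes
  out
}
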