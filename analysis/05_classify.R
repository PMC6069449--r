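#!/usr/bin/env Rscript
# Supervised RBF-SVM classification of the corrected cube, trained on
# survey-pixel spectra plus analyst-picked background regions, with an
# unsupervised k-means baseline for refinement flags. Writes the class map
# (with and without spume exclusion) and the training manifest.

source("analysis/00_config.R")

corrected <- read_cube(out_path("reflectance_corrected"))
survey <- read_survey_csv(scene_path("survey.csv"))
survey <- georeference_survey(survey, corrected$gt,
                              dim(corrected$values)[1:2])
labels_raster <- read_band_raster(scene_path("truth_labels"))
legend <- attr(labels_raster, "legend")
truth_labels <- matrix(legend[labels_raster], nrow(labels_raster))
spume_poly <- utils::read.csv(scene_path("spume_polygon.csv"))

d <- dim(corrected$values)
work <- denoise(corrected, spectral_window = 5, spatial_window = 1)

# analyst-picked background regions: a handful of pixels per background
# class, taken where the truth raster is unambiguous
set.seed(cfg$seed + 3)
m <- matrix(work$values, d[1] * d[2], d[3])
bx <- NULL; bl <- character(0)
for (cl in c("sand", cfg$background)) {
  ix <- sample(which(truth_labels == cl), 12)
  bx <- rbind(bx, m[ix, ])
  bl <- c(bl, rep(cl, 12))
}

tx <- t(vapply(seq_len(nrow(survey)), function(i) {
  pixel_spectrum(work, survey$pixel_y[i], survey$pixel_x[i])
}, numeric(d[3])))
tl <- coral_class_label(survey$coral_type, survey$bleaching_level)

model <- train_classifier(rbind(tx, bx), c(tl, bl))
print(model)
cmap <- predict_map(model, work)

foam <- rasterize_polygons(list(spume_poly), corrected$gt, d[1:2])
cmap_excl <- apply_exclusion_mask(cmap, foam)

write_band_raster(ifelse(is.na(cmap$ids), 0L, cmap$ids),
                  out_path("class_map"), corrected$gt, legend = cmap$legend)
write_band_raster(ifelse(is.na(cmap_excl$ids), 0L, cmap_excl$ids),
                  out_path("class_map_excluded"), corrected$gt,
                  legend = cmap_excl$legend)

baseline <- unsupervised_baseline(work, k = length(cmap$legend),
                                  seed = cfg$seed + 4)
flags <- refinement_flags(cmap, baseline)
cat(sprintf("unsupervised refinement flags raised at %d of %d pixels\n",
            sum(flags), length(flags)))

utils::write.csv(data.frame(class = c(tl, bl)),
                 out_path("training_manifest.csv"), row.names = FALSE)
cat(sprintf("trained on %d spectra (%d survey + %d background), %d classes\n",
            nrow(tx) + nrow(bx), nrow(tx), nrow(bx),
            length(model$legend)))
cat("wrote class maps to", out_path("class_map"), "(+ _excluded)\n")
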