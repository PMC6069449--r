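#!/usr/bin/env Rscript
# Simulate a shallow-reef scene with known ground truth: six coral classes
# (two genera at three bleaching levels each) over a sand background with a
# dark benthos patch, a 0-3 m depth gradient, a spume band over one coral
# blob, and sensor noise. Writes the full bundle (ENVI cube, truth rasters,
# survey CSV, white reference, spume polygon, config echo) under
# results/scene/.

source("analysis/00_config.R")

lib <- synth_endmembers(cfg$genera, 1:6, seed = cfg$seed, grid = grid)
truth <- make_scene(cfg$shape, c(cfg$coral_classes, cfg$background),
                    cfg$max_depth, seed = cfg$seed, library = lib)

# a spume (sea foam) band across half of the Porites lv6 blob
px <- which(truth$labels == "Porites massive lv6", arr.ind = TRUE) - 1
r0 <- range(px[, 1]); c0 <- range(px[, 2])
corners <- rbind(c(r0[1] - 0.5, c0[1] - 0.5), c(r0[1] - 0.5, mean(c0)),
                 c(r0[2] + 0.5, mean(c0)), c(r0[2] + 0.5, c0[1] - 0.5))
geo <- pixel_to_geo(truth$gt, corners[, 1], corners[, 2])
spume_poly <- data.frame(lat = geo$lat, lon = geo$lon)
truth_spumed <- add_spume(truth, list(spume_poly))

rend <- render_cube(truth_spumed, water, noise_sd = cfg$noise_sd,
                    seed = cfg$seed + 1)

# the in-water survey: divers log coral points; none are collected under
# the foam band (no usable reference photos there)
survey <- make_survey_table(truth, cfg$n_survey, seed = cfg$seed + 2)
foam <- rasterize_polygons(list(spume_poly), truth$gt, dim(truth$labels))
survey <- survey[!foam[cbind(survey$pixel_y + 1L, survey$pixel_x + 1L)], ]

write_cube(rend$cube, scene_path("cube"), "bil")
write_white_reference(rend$white, grid, scene_path("white_reference.csv"))
write_survey_csv(survey, scene_path("survey.csv"))
write_band_raster(matrix(match(truth$labels, colnames(lib$spectra)),
                         nrow(truth$labels)),
                  scene_path("truth_labels"), truth$gt,
                  legend = colnames(lib$spectra))
write_band_raster(truth$depth, scene_path("truth_depth"), truth$gt)
utils::write.csv(spume_poly, scene_path("spume_polygon.csv"),
                 row.names = FALSE)
writeLines(c(sprintf("seed = %d", cfg$seed),
             sprintf("shape = %d x %d", cfg$shape[1], cfg$shape[2]),
             sprintf("bands = %d (%g-%g nm)", cfg$n_bands, cfg$lambda_min,
                     cfg$lambda_max),
             sprintf("max_depth = %g m", cfg$max_depth),
             sprintf("noise_sd = %g", cfg$noise_sd),
             sprintf("classes = %s", paste(cfg$coral_classes,
                                           collapse = "; "))),
           scene_path("config_echo.txt"))

cat(sprintf("scene: %d x %d pixels, %d bands, %d survey records kept (%d drawn)\n",
            cfg$shape[1], cfg$shape[2], cfg$n_bands, nrow(survey),
            cfg$n_survey))
cat(sprintf("spume band covers %d pixels, %d of them over coral\n",
            sum(foam), sum(foam & is_coral_label(truth$labels))))
cat("wrote scene bundle to", cfg$scene_dir, "\n")
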