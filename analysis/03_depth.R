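#!/usr/bin/env Rscript
# Estimate relative depth from the blue/green log ratio, calibrate it
# against the survey depths, and correct the reflectance cube for
# water-column variance. Reports the calibration line and the agreement
# with the scene's true depth raster.

source("analysis/00_config.R")

refl <- read_cube(out_path("reflectance"))
survey <- read_survey_csv(scene_path("survey.csv"))
survey <- georeference_survey(survey, refl$gt, dim(refl$values)[1:2])
truth_depth <- read_band_raster(scene_path("truth_depth"))

wcm <- water_column_model()
relmap <- relative_depth_log_ratio(refl, wcm)
depth <- calibrate_depth(relmap, survey)
corrected <- depth_correct(refl, model = wcm)

write_band_raster(ifelse(depth$valid, depth$values, -1),
                  out_path("depth_calibrated"), refl$gt)
write_cube(corrected, out_path("reflectance_corrected"), "bil")
utils::write.csv(data.frame(intercept = depth$calibration$intercept,
                            slope = depth$calibration$slope,
                            n_points = depth$calibration$n,
                            rmse_m = depth$calibration$rmse),
                 out_path("depth_calibration.csv"), row.names = FALSE)

ok <- depth$valid
rho <- cor(depth$values[ok], truth_depth[ok], method = "spearman")
mae <- mean(abs(depth$values[ok] - truth_depth[ok]))
cat(sprintf("calibration: depth = %.3f + %.3f * index (n = %d, rmse %.3f m)\n",
            depth$calibration$intercept, depth$calibration$slope,
            depth$calibration$n, depth$calibration$rmse))
cat(sprintf("vs truth: Spearman rho = %.4f, MAE = %.3f m (%.1f%% of max depth)\n",
            rho, mae, 100 * mae / max(truth_depth)))
cat(sprintf("invalid pixels: %d of %d\n", sum(!ok), length(ok)))
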