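# Shared configuration for the numbered analysis drivers.
# All drivers are run from the repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_reflectance.R
#   ...
# Every driver is a thin narrative over the reefbleach package; outputs land
# under results/.

library(reefbleach)

cfg <- list(
  seed = 2026,
  shape = c(96, 96),
  n_bands = 274, lambda_min = 400, lambda_max = 1000,
  genera = c("Acropora", "Porites massive"),
  coral_classes = c("Acropora lv1", "Acropora lv3", "Acropora lv5",
                    "Porites massive lv2", "Porites massive lv4",
                    "Porites massive lv6"),
  background = "benthos",
  max_depth = 3,       # m; within the band-ratio method's reliable range
  noise_sd = 0.005,    # reflectance units
  n_survey = 64,
  scene_dir = "results/scene",
  out_dir = "results"
)

dir.create(cfg$scene_dir, recursive = TRUE, showWarnings = FALSE)

grid <- make_wavelength_grid(cfg$n_bands, cfg$lambda_min, cfg$lambda_max)
water <- make_water_model(grid)

scene_path <- function(...) file.path(cfg$scene_dir, ...)
out_path <- function(...) file.path(cfg$out_dir, ...)
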