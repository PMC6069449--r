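Package: reefbleach
Title: Hyperspectral Coral-Bleaching Mapping from Shallow-Reef Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for mapping coral genera and bleaching
    severity from georeferenced visible/near-infrared hyperspectral
    datacubes of shallow reefs. Simulates synthetic reef scenes with known
    ground truth (per-genus, per-bleaching-level endmember spectra,
    Beer-Lambert water-column attenuation, sensor noise), reads and writes
    ENVI-style cubes and in-water survey attribute tables, converts
    radiance to reflectance against a white reference, estimates relative
    depth from the blue/green log ratio and corrects reflectance for
    water-column variance, extracts mean spectral signatures at survey
    points, evaluates a registry of normalized-difference bleaching
    indices, classifies pixels with a radial-basis-function support vector
    machine, and assembles thematic-map accuracy reports with
    excessive-area flagging and spume-exclusion masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    mgcv,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
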