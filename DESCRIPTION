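Package: phytopet
Title: Quantitative Analysis of Dynamic PET Radiotracer Transport in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying radiotracer transport in plants imaged by
    dynamic positron emission tomography (PET) with CT-guided region
    delineation. Provides NIfTI-1 volume input/output with voxel-grid
    geometry, construction of prism regions of interest from heights
    measured in CT space, time-activity-curve extraction with physical
    decay correction, per-plant normalization and uptake-rate estimation
    by first central differences, a circular-shift permutation test for
    diurnal (light/dark) modulation of uptake, validation of attenuation
    correction against known administered doses, and reference-source
    drift checks. Includes a synthetic 4D phantom generator that simulates
    sodium-22 root-to-shoot translocation under nutrient and
    channel-inhibitor treatments with attenuation, Poisson counting noise
    and physical decay, so every analysis stage can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
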