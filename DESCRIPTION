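Package: bioalbedo
Title: Glacier-Algal Photophysiology, Radiative Forcing and Ice-Surface Darkening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the photophysiology and pigmentation of glacier
    algae to ice-surface energy absorption, melt generation, bloom development
    and albedo. Fits rapid light curves (Platt-type photoinhibition or Webb
    exponential models) with a phenolic-shading correction that converts
    whole-cell to chloroplast-level light response, calibrates pigment
    mass-specific absorption spectra and reconstructs single-cell absorption
    cross-sections, computes a per-cell spectral energy budget with an
    empirical pigment-packaging correction, converts population absorption to
    instantaneous radiative forcing and meltwater equivalent, simulates
    threshold-gated logistic bloom dynamics from hourly environmental forcing,
    and estimates spectral and visible broadband albedo of a layered ice
    column with a delta-Eddington two-stream solver. A seeded synthetic-data
    module generates every input the analysis chain consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
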