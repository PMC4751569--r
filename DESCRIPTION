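Package: fibrilMPL
Title: Mass-per-Unit-Length Densitometry for Filaments in Dark-Field TEM Images
Version: 0.1.0
Authors@R:
    person("Astbury", "Imaging", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the mass per unit length (MPL) of filamentous
    assemblies such as amyloid fibrils from tilted-beam dark-field
    transmission electron micrographs, calibrated against an in-image
    standard of known MPL (typically tobacco mosaic virus, 131 kDa/nm).
    Selections of standards and fibrils are straight line segments with a
    band width; intensities are sampled along one-pixel perpendicular
    slices with two flanking background bands, background-corrected, and
    ratioed against the pooled standard intensity. Includes a synthetic
    bar-phantom generator with Gaussian noise for validation, a width-sweep
    robustness analysis, a background-fluctuation error statistic, plain-text
    TSV outputs, and a command-line interface. Reads and writes single-channel
    TIFF (8/16-bit integer and 32-bit float) and PNG (8/16-bit) images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
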