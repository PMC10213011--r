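Package: benthicready
Title: Analysis-Ready Preprocessing of Benthic Seafloor Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw towed-camera seafloor photographs into analysis-ready
    images that are semantically comparable as sampling units. Implements
    batch-wise z-score light-cone (vignetting) correction, contrast-limited
    adaptive histogram equalization, reference-based channel-wise histogram
    matching for color normalization, red-laser-point detection for
    pixels-per-centimeter scale estimation, and rescaling plus center
    cropping to a common spatial footprint. Includes the technical-validation
    metrics (per-channel RMS contrast, median intensity, footprint variance),
    a metadata table reader for the accompanying per-image CSV schema, a
    ground-truthed synthetic seafloor image generator for end-to-end testing,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
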