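Package: minfluxr
Title: Analysis and Simulation of DNA-PAINT MINFLUX Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and quantification of MINFLUX single-molecule
    localization exports acquired with DNA-PAINT labeling. Groups repeated
    localizations into binding events via trace identifiers, computes the
    time between events, median center-frequency ratio (CFR) and background
    emission frequency, estimates per-event and combined localization
    precisions, corrects sample drift by redundant cross-correlation of
    time-windowed renderings, and measures image resolution by Fourier ring
    correlation with the one-seventh criterion. Includes a physical
    simulator of the CFR based on vectorial (Richards-Wolf) focus field
    calculations of the donut excitation and confocal detection point
    spread functions, a synthetic acquisition generator with known ground
    truth for validating every estimator, and 2D histogram / 3D Gaussian
    rendering of localization data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
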