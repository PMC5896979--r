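Package: confinetrack
Title: Automated Analysis of Confined Cell Migration and Nuclear Envelope
    Rupture in Microfluidic Constriction Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of multi-channel time-lapse microscopy of
    cells migrating through microfluidic constriction devices. Registers the
    device geometry from the transmitted-light channel with a circular Hough
    transform, stabilizes the sequence against stage drift by normalized
    cross-correlation, segments fluorescently labeled nuclei with adaptive
    thresholding and distance-transform watershed (with h-minima suppression
    and protection of dumbbell-shaped nuclei inside constrictions), tracks
    nuclei frame to frame with a greedy distance/intensity/area cost, and
    detects constriction-transit events, transit times, nuclear envelope
    rupture and repair from the chromatin-marker/nucleoplasmic-reporter
    intensity ratio, and cell divisions. Includes a synthetic time-lapse
    generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
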