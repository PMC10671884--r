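Package: avlr
Title: Arteriovenous Length Ratio Morphometry for Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometric analysis of the retinal vasculature from fundus
    images with artery/vein-labeled vessel maps. Localizes the optic disc,
    cuts annular regions of interest in optic-disc-radius units, thins the
    vasculature to one-pixel centerlines, extracts optimized vessel segments
    between branch points, computes nine per-segment length and tortuosity
    metrics (chord, arc, distance metric, inflection count metrics, sum of
    angles, curvature norms, centerline length), aggregates them into
    image-level arteriovenous length ratio (AVLR) features, and compares
    feature records between left and right eyes. Includes a synthetic
    phantom generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
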