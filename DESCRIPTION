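Package: trilogrowth
Title: Axial Growth and Trunk Segmentation Dynamics in Trilobite Ontogenies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing post-embryonic axial growth in trilobites and
    other hemianamorphic arthropods from cross-sectional specimen measurements.
    Provides a specimen measurement schema with CSV input/output and derived
    axial quantities (cephalic, trunk and body lengths, relative segment
    lengths and boundary positions, per-stage growth rates); major-axis
    regression profiles of per-segment allometric coefficients; two-phase
    (single change point) segmented log-log regression with maximum-likelihood
    grid search and bootstrap confidence intervals; segmental-gradient (SG) and
    trunk-gradient (TG) models of thoracic segment growth fitted by
    Levenberg-Marquardt nonlinear least squares and compared with AICc and
    Akaike weights; a seeded synthetic ontogeny generator emulating a meraspid
    series with decreasing per-moult trunk growth and pygidial size stasis; and
    an end-to-end analysis pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
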