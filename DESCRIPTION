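Package: denscape
Title: Alpine Brown Bear Den Habitat Selection and Heli-Ski Disturbance Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to model brown bear (Ursus arctos) den-site selection in
    alpine terrain with used-available resource selection functions (RSF).
    Derives terrain and climate covariates (slope, aspect, topographic
    position, vector ruggedness, wetness index, clear-sky solar radiation,
    snow-load index, vegetation height) from digital terrain and surface
    models, fits and ranks a priori candidate logistic models by AICc,
    validates them with binned k-fold Spearman cross-validation, classifies
    the RSF surface into equal-area habitat classes, and overlays a
    helicopter-activity kernel-density surface to map disturbance risk.
    Includes a synthetic-landscape simulator (spectral-synthesis DEM, canopy,
    glaciers, survey route, flight tracks, dens drawn from a known selection
    function) so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    MASS,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
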