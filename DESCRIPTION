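Package: ctiq
Title: Quantitative CT Image Quality Assessment and Protocol Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Task-based image quality assessment for computed tomography and a
    procedure to harmonize scan protocols across scanners from different
    vendors. Estimates the 2D noise power spectrum (NPS) from uniform phantom
    regions with per-ROI polynomial detrending, derives noise and texture
    metrics (noise SD, NPS peak, peak frequency, mean frequency, area under
    the radial NPS), measures insert contrast and contrast-to-noise ratio,
    estimates the task transfer function (TTF) from circular-edge inserts
    including a parametric sigmoid-plus-Gaussians edge model for low-CNR
    edges, and computes the non-prewhitening-with-eye-filter (NPWE) model
    observer detectability index with conversion to ROC area under the curve.
    A built-in phantom simulator generates series with known noise spectra,
    dose scaling and parametric iterative-reconstruction emulation, so the
    whole harmonization chain (NPS-matched dose rescaling, image-quality
    change ratios, Spearman-based iterative-reconstruction level matching)
    can be exercised end to end with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
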