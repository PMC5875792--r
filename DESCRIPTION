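Package: facile
Title: Fourier-Domain Analysis of Stimulus-Locked Calcium Imaging in the Living Eye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and quantification of stimulus-locked neuronal
    responses from in vivo adaptive-optics calcium-imaging videos of the
    retina. Computes per-pixel and per-cell fundamental-harmonic (F1/F0)
    response amplitude and phase at the stimulus frequency, calls
    significance against a high-frequency noise band (mean plus three SD),
    classifies ON/OFF polarity from response phase, applies Rayleigh
    circular statistics to phase distributions, performs frame-wise rigid
    motion correction, matches cells across imaging sessions, and
    reproduces retinal light-dosimetry arithmetic (irradiance, numerical-
    aperture power equivalence, areal cell-density expectations). Includes
    a synthetic video generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    clue,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
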