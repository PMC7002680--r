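Package: seer
Title: Spectrally Encoded Enhanced Representations of Hyperspectral
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phasor-based compression of hyperspectral fluorescence image
    cubes into enhanced RGB visualizations (SEER). Transforms per-pixel
    emission spectra into spectral phasor coordinates, denoises in phasor
    space, and assigns colors through standard reference maps (gradient
    descent/ascent, radial, angular), a tensor (gradient-of-counts) map,
    and adaptive scale/morph contrast modes. Includes the baseline
    Gaussian-kernel TrueColor and peak-wavelength renderings, no-reference
    color image quality metrics (colorfulness, EME sharpness, AME contrast,
    CQE), a spectral-separation-accuracy statistic, and a simulated
    hyperspectral test chart generator with Poisson and detector noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tiff,
    tools
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
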