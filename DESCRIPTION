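Package: subshift
Title: Fast Subpixel Translation Registration by Decimated Phase
    Correlation and Single-Step DFT Upsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rigid translation registration of 2-D grayscale images (for
    example multimodal brain scans) to subpixel accuracy.  A coarse
    pixel-level estimate is obtained from the inverse transform of a
    K-decimated, normalized cross-power spectrum, with explicit handling
    of the aliasing ambiguity that decimation introduces.  The estimate
    is then refined on an upsampled 1.5 x 1.5 pixel lag window evaluated
    directly as a product of three DFT matrices (no global
    zero-padding), using a bidirectional row search that avoids
    materializing the full window.  Includes the classic two-step
    upsampled cross-correlation baseline, registration quality metrics
    (scale-minimized NRMSE and RMS gray-value target registration
    error), a band-limited synthetic benchmark generator with exact
    Fourier-shift ground truth, PNG/TIFF image input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
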