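Package: scaletomo
Title: Stitching, Segmentation and Microstructure Statistics for
    Whole-Scale X-ray Nano-Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing chain for whole-sample X-ray nano-holotomography of
    porous biological microstructures such as ultra-white beetle scales.
    Assembles overlapping tomography sub-scans into a single greyscale
    matrix (overlap-frame matching by normalized cross-correlation,
    centre-of-overlap seams, principal-axis tilt correction with cubic
    interpolation), segments it into a chitin/air binary volume
    (percentile saturation, halo-correct chunked 3-D non-local means
    denoising, adaptive Gaussian plus global thresholding), and computes
    porous-network statistics (filling fraction with cube-sampling
    uncertainty, directional two-point correlation functions,
    representative-cube selection).  Includes a seeded synthetic
    porous-scale generator so the full pipeline can be exercised and
    validated at desk scale, plus bit-packed binary volume and NPY/zip
    container input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
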