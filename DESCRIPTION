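Package: petdec
Title: Deconvolution Scatter Correction for 2D-Rebinned Brain PET Sinograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating convolution-subtraction (deconvolution)
    scatter correction of 2D-rebinned positron emission tomography sinograms
    against a hybrid dual-energy-window reference method. Includes a synthetic
    phantom and sinogram simulator with known scatter ground truth, the
    frequency-domain scatter kernel and its tail-matching calibration,
    attenuation correction and filtered back projection, oxygen-15
    quantification (cerebral blood flow, blood volume, oxygen extraction
    fraction and metabolic rate of oxygen), and the comparison statistics
    used to assess agreement between scatter correction methods (slice-wise
    percent-difference profiles, region-of-interest tables, intraclass
    correlation and geometric mean regression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
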