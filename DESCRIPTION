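Package: pbshalo
Title: Spot Halo Characterization and Field Size Factors for Proton Pencil-Beam Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the low-intensity halo of proton
    pencil-beam-scanning spots and predicting field size factors (FSFs).
    Implements high-dynamic-range compositing of multi-exposure spot images
    (the pair-magnification technique), registration with sub-pixel refinement,
    radially averaged profile extraction with angular masking of detector
    artifacts, full-width metrics (FWHM, FW10%, FW1%), and spot-superposition
    FSF calculation for square scanned fields, comparing single-Gaussian beam
    models against halo-included profiles. Includes a synthetic-data generator
    emulating film and scintillator-CCD measurements (dynamic-range clipping,
    directional over-response, multiplicative noise) so the full chain is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
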