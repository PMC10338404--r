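Package: amadoriNMR
Title: Detection and Quantification of Protein Glycation in 2D HSQC Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and quantifies glucose-induced glycation (Amadori
    products, fructoselysine) in denatured proteins from multiplicity-edited
    1H-13C HSQC spectra. Provides a chemical-shift fingerprint library for the
    cyclic forms of the Amadori product, readers for Sparky and CSV peak lists
    and for gridded 2D spectra, peak picking and 2D Gaussian lineshape
    integration, fingerprint matching with configurable tolerances,
    per-proton-normalized stoichiometry estimation with strict CH/CH2
    multiplicity-class separation, a concentration-based detection-limit
    model, and a synthetic spectrum generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
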