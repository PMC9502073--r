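Package: pkacn
Title: Linear pKa Calibration and the Gibbs Energy of the Proton in Acetonitrile
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thermodynamic-cycle pKa prediction of neutral organic
    (super)bases in acetonitrile from computed gas-phase and solvation Gibbs
    energies.  Reduced basicities of base/conjugate-acid pairs are calibrated
    against experimental pKa by per-class, per-method linear regression; the
    calibrations are converted to energy units and a second regression of the
    intercept on the slope, extrapolated to the ideal slope, recovers the total
    Gibbs energy of the solvated proton without any external reference value.
    Includes shipped calibration presets for nitrogen, phosphorus and carbon
    bases, a synthetic-data generator with known ground truth for end-to-end
    validation, delimited-table input/output and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
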