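Package: nirmaize
Title: Near-Infrared Chemometrics for Maize Protein Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A chemometrics toolkit for predicting protein content in maize
    powder from near-infrared (NIR) absorbance spectra. Implements scatter
    correction (MSC, SNV), derivative and Savitzky-Golay preprocessing and
    their compositions, SPXY calibration/validation partitioning, partial
    least squares regression (NIPALS) with cross-validated latent-variable
    selection, grid-searched support vector regression, four wavelength
    selection algorithms (regression-coefficient ranking, competitive
    adaptive reweighted sampling, the successive projections algorithm and
    uninformative variable elimination), and R/RMSE/RPD model evaluation.
    Ships a synthetic NIR spectrum generator with known ground truth so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
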