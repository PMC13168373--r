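Package: luquant
Title: Quantitative Lu-177 SPECT/CT Calibration and Image-Quality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative Lu-177 SPECT/CT quality control across
    scanners and sites: parametric uniform-cylinder and NEMA IQ phantom
    models with voxelization, a synthetic reconstruction simulator
    (Gaussian or difference-of-Gaussians point-spread function, count-targeted
    Poisson noise, counts or Bq/mL output), image calibration factors
    (cps/MBq) and correction factors for quantitative images, sphere
    recovery coefficients and recovery bands, Gibbs ringing strength from
    smoothing-spline radial profiles, and radionuclide-calibrator metrology
    (session statistics, dial-setting correction, vial-geometry correction
    factors, and expanded uncertainty budgets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
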